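# short shared stimulus for the reverse-correlation tests
stim120 <- checkerboard_stimulus(duration_s = 120, seed = 17)

test_that("a single event recovers the mean-subtracted stimulus segment", {
  n_bins <- 120 * 60
  trace <- numeric(n_bins)
  t_ev <- 3000L
  trace[t_ev] <- 1
  strf <- reverse_correlate(trace, stim120)
  S <- matrix(stim120$frames, nrow = length(stim120$el) * length(stim120$az))
  mu <- rowMeans(S)
  for (l in c(0L, 7L, 29L)) {
    f <- min(floor((t_ev - l - 1) / 60 * 4) + 1, ncol(S))
    want <- matrix(S[, f] - mu, nrow = length(stim120$el))
    expect_equal(strf$rf[, , l + 1], want, tolerance = 1e-12)
  }
})

test_that("unnormalized reverse correlation is linear in the trace", {
  n_bins <- 120 * 60
  set.seed(2)
  x <- rpois(n_bins, 0.1)
  y <- rpois(n_bins, 0.1)
  sx <- reverse_correlate(x, stim120, normalize = FALSE)
  sy <- reverse_correlate(y, stim120, normalize = FALSE)
  sxy <- reverse_correlate(2 * x + 3 * y, stim120, normalize = FALSE)
  expect_equal(sxy$rf, 2 * sx$rf + 3 * sy$rf, tolerance = 1e-9)
})

test_that("degenerate traces are rejected with clear errors", {
  expect_error(reverse_correlate(numeric(120 * 60), stim120), "all-zero")
  expect_error(reverse_correlate(rep(1, 500), stim120), "span")
})

test_that("a linear cell's kernel is recovered from a synthetic recording", {
  truth <- list(list(center_az = 10, center_el = 5, sd_long = 2.4,
                     sd_short = 2.4, orientation = 0, peak_latency_ms = 100))
  stim <- checkerboard_stimulus(duration_s = 600, seed = 23)
  rec <- synth_recording(truth, stim, seed = 29)
  strf <- reverse_correlate(rec$traces[, 1], stim)
  peak <- strf$rf[, , strf$peak_bin]
  want <- render_gaussian_frame(stim$az, stim$el, 10, 5, 2.4, 2.4)
  expect_gt(cor(as.numeric(peak), as.numeric(want)), 0.7)
  rf <- fit_rf_gaussian(strf)
  expect_true(rf$fit_ok)
  err <- sqrt((rf$center_az - 10)^2 + (rf$center_el - 5)^2)
  expect_lt(err, 3.7)  # within one stimulus field width
  # latency of the temporal kernel is found
  expect_lt(abs(strf$peak_latency_ms - 100), 50)
})

test_that("an unmodulated trace is indistinguishable from the shuffled null", {
  trace <- rep(1, 120 * 60)
  trace[1] <- 1 + 1e-9  # dodge the all-zero guard without adding signal
  strf <- reverse_correlate(trace, stim120)
  z <- rf_peak_zscore(trace, stim120, strf, n_shuffle = 100, seed = 3)
  expect_lt(abs(z), 3)
})

test_that("Gaussian fits are exact on noise-free frames and a fixed point", {
  stim <- stim120
  frame <- render_gaussian_frame(stim$az, stim$el, 10, 5, 2.4, 2.4)
  rf <- fit_rf_gaussian(frame_strf(frame, stim$az, stim$el))
  expect_true(rf$fit_ok)
  expect_lt(abs(rf$center_az - 10), 0.1)
  expect_lt(abs(rf$center_el - 5), 0.1)
  expect_equal(rf$size, 4.8, tolerance = 1e-3)

  # sd_long 3, sd_short 2 -> size 5; orientation recovered mod pi
  f2 <- render_gaussian_frame(stim$az, stim$el, -5, 2, 3, 2, theta = 0.6)
  rf2 <- fit_rf_gaussian(frame_strf(f2, stim$az, stim$el))
  expect_equal(rf2$size, 5, tolerance = 1e-3)
  expect_lt(min(abs(rf2$orientation - 0.6), pi - abs(rf2$orientation - 0.6)),
            0.05)
  expect_equal(rf2$size, rf2$sd_long + rf2$sd_short, tolerance = 1e-9)

  # fit -> synthesize -> fit is a fixed point
  f3 <- render_gaussian_frame(stim$az, stim$el, rf2$center_az, rf2$center_el,
                              rf2$sd_long, rf2$sd_short, rf2$orientation,
                              amp = rf2$amplitude, offset = rf2$offset)
  rf3 <- fit_rf_gaussian(frame_strf(f3, stim$az, stim$el))
  expect_equal(rf3$center_az, rf2$center_az, tolerance = 1e-6)
  expect_equal(rf3$sd_long, rf2$sd_long, tolerance = 1e-6)
  expect_equal(rf3$size, rf2$size, tolerance = 1e-6)
})

test_that("noisy frames still localize the center within one field", {
  stim <- stim120
  ok <- vapply(1:100, function(s) {
    set.seed(400 + s)
    f <- render_gaussian_frame(stim$az, stim$el, -8, 3, 2.4, 2.4) +
      matrix(rnorm(length(stim$el) * length(stim$az), sd = 0.2),
             nrow = length(stim$el))
    rf <- fit_rf_gaussian(frame_strf(f, stim$az, stim$el))
    isTRUE(rf$fit_ok) &&
      sqrt((rf$center_az + 8)^2 + (rf$center_el - 3)^2) < 3.7
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("screen filter drops border/off-screen centers and weak recordings", {
  stim <- stim120
  rfs <- data.frame(roi_id = as.character(1:3),
                    az = c(40, 0, -34), el = c(0, 0, 0))
  out <- screen_filter(rfs, stim)
  expect_false("1" %in% out$kept)   # off screen
  expect_false("3" %in% out$kept)   # border column
  expect_true("2" %in% out$kept)
  expect_true(out$recording_excluded)  # only 1 survivor < 10

  interior <- data.frame(roi_id = as.character(1:12),
                         az = seq(-20, 20, length.out = 12),
                         el = rep(c(-5, 5), 6))
  out2 <- screen_filter(interior, stim)
  expect_length(out2$kept, 12)
  expect_false(out2$recording_excluded)
  out9 <- screen_filter(interior[1:9, ], stim)
  expect_true(out9$recording_excluded)
  empty <- screen_filter(interior[0, ], stim)
  expect_true(empty$recording_excluded)
})

test_that("synthetic recordings are deterministic and respect gain = 0", {
  truth <- list(list(center_az = 0, center_el = 0, sd_long = 2.4,
                     sd_short = 2.4, orientation = 0, peak_latency_ms = 100))
  r1 <- synth_recording(truth, stim120, gain = 4, seed = 5)
  r2 <- synth_recording(truth, stim120, gain = 4, seed = 5)
  expect_identical(r1$traces, r2$traces)
  expect_equal(nrow(r1$traces), 120 * 60)
  expect_true(all(r1$rates >= 0))

  r0 <- synth_recording(truth, stim120, gain = 0, baseline = -1, seed = 5)
  expect_equal(unique(as.numeric(r0$rates)), log1p(exp(-1)))
  expect_error(synth_recording(list(), stim120), "empty")
  bad <- list(list(center_az = NaN, center_el = 0, sd_long = 2, sd_short = 2,
                   orientation = 0, peak_latency_ms = 100))
  expect_error(synth_recording(bad, stim120), "finite")
})
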