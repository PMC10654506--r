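#' Reverse-correlation estimate of a spatiotemporal receptive field
#'
#' Computes the response-weighted average of the (mean-subtracted)
#' checkerboard stimulus over a pre-response window: for each lag bin, the
#' average of the stimulus frames preceding each analysis bin, weighted by
#' the deconvolved activity in that bin. The activity trace is expected at
#' the analysis resolution (one sample per `bin` seconds, 16.7 ms by
#' default); the 4 Hz stimulus is held piecewise-constant across analysis
#' bins. The peak latency is the lag whose spatial frame carries the most
#' deviation-from-mean energy.
#'
#' @param trace numeric activity series (nonnegative event rates/counts),
#'   one value per analysis bin, aligned to stimulus onset.
#' @param stimulus a `stimulus_ensemble`.
#' @param window pre-response window, seconds (default 0.5).
#' @param bin analysis bin width, seconds (default 1/60, i.e. 16.7 ms).
#' @param normalize divide by the total event weight (default TRUE, the
#'   response-weighted *average*); `FALSE` gives the raw weighted sum,
#'   which is linear in the trace.
#' @return an `strf`: list with `rf` (ny x nx x n_lags array), `az`, `el`
#'   (field centers, deg), `energy` (per-lag spatial energy), `peak_bin`,
#'   `peak_latency_ms`, `bin_s`, `window_s`, `total_weight`.
#' @export
reverse_correlate <- function(trace, stimulus, window = 0.5, bin = 1 / 60,
                              normalize = TRUE) {
  stopifnot(inherits(stimulus, "stimulus_ensemble"))
  trace <- as.numeric(trace)
  n_frames <- dim(stimulus$frames)[3L]
  t_stim <- n_frames / stimulus$rate
  t_trace <- length(trace) * bin
  if (abs(t_stim - t_trace) > 1 / stimulus$rate + 1e-9)
    stop(sprintf(
      "trace (%.1f s) and stimulus (%.1f s) do not cover the same span",
      t_trace, t_stim))
  if (!any(trace != 0)) stop("all-zero trace: no events to correlate on")
  if (any(trace < 0)) stop("trace must be nonnegative")

  ny <- dim(stimulus$frames)[1L]
  nx <- dim(stimulus$frames)[2L]
  S <- matrix(stimulus$frames, nrow = ny * nx, ncol = n_frames)
  mu <- rowMeans(S)
  n_lags <- as.integer(round(window / bin))
  fmap <- pmin(floor((seq_along(trace) - 1) * bin * stimulus$rate) + 1,
               n_frames)

  rf <- array(0, dim = c(ny, nx, n_lags))
  energy <- numeric(n_lags)
  for (l in seq_len(n_lags) - 1L) {
    tt <- (l + 1L):length(trace)
    w_by_frame <- frame_weights(trace[tt], fmap[tt - l], n_frames)
    w_tot <- sum(trace[tt])
    sta <- as.numeric(S %*% w_by_frame) - mu * w_tot
    if (normalize && w_tot > 0) sta <- sta / w_tot
    rf[, , l + 1L] <- sta
    energy[l + 1L] <- sum(sta^2)
  }
  peak_bin <- which.max(energy)
  structure(list(
    rf = rf, az = stimulus$az, el = stimulus$el,
    energy = energy, peak_bin = peak_bin,
    peak_latency_ms = (peak_bin - 1L) * bin * 1000,
    bin_s = bin, window_s = window,
    total_weight = sum(trace)
  ), class = "strf")
}

# sum trace weights per stimulus frame index (length n_frames vector)
frame_weights <- function(w, frame_idx, n_frames) {
  out <- numeric(n_frames)
  agg <- rowsum(w, frame_idx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' @export
print.strf <- function(x, ...) {
  cat(sprintf("STRF: %d x %d fields, %d lag bins, peak latency %.0f ms\n",
              dim(x$rf)[2L], dim(x$rf)[1L], dim(x$rf)[3L], x$peak_latency_ms))
  invisible(x)
}

#' Elliptical 2D Gaussian fit of the peak-latency receptive-field frame
#'
#' Fits a six-parameter elliptical Gaussian (signed amplitude, center,
#' two SDs, orientation, plus offset) to the spatial frame at the peak
#' latency by Levenberg-Marquardt nonlinear least squares, initialized at
#' the frame's extremum. The RF size convention is the mean of the long- and
#' short-axis diameters at 1 SD, i.e. `sd_long + sd_short`. Divergent fits
#' or SDs exceeding the screen half-extent are flagged (`fit_ok = FALSE`)
#' so the cell can be excluded downstream.
#'
#' @param strf an `strf` from [reverse_correlate()].
#' @return a `receptive_field`: list with `center_az`, `center_el`,
#'   `sd_long`, `sd_short`, `orientation` (radians, long axis, in
#'   `[0, pi)`), `amplitude`, `offset`, `peak_latency_ms`, `size`
#'   (= sd_long + sd_short, deg), `fit_ok`.
#' @export
fit_rf_gaussian <- function(strf) {
  stopifnot(inherits(strf, "strf"))
  frame <- strf$rf[, , strf$peak_bin]
  if (!all(is.finite(frame))) stop("peak frame contains non-finite values")
  grid <- expand.grid(el = strf$el, az = strf$az)
  dat <- data.frame(z = as.numeric(frame), x = grid$az, y = grid$el)

  i0 <- which.max(abs(dat$z - median(dat$z)))
  start <- list(A = dat$z[i0] - median(dat$z), x0 = dat$x[i0],
                y0 = dat$y[i0], sx = strf$az[2L] - strf$az[1L],
                sy = strf$el[2L] - strf$el[1L], th = 0,
                off = median(dat$z))
  half_az <- (max(strf$az) - min(strf$az)) / 2 + (strf$az[2L] - strf$az[1L])

  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ off + A * exp(-0.5 * (((cos(th) * (x - x0) + sin(th) * (y - y0)) / sx)^2 +
                                ((-sin(th) * (x - x0) + cos(th) * (y - y0)) / sy)^2)),
      data = dat, start = start,
      lower = c(A = -Inf, x0 = min(dat$x) - half_az, y0 = min(dat$y) - half_az,
                sx = 0.2, sy = 0.2, th = -pi, off = -Inf),
      upper = c(A = Inf, x0 = max(dat$x) + half_az, y0 = max(dat$y) + half_az,
                sx = 4 * half_az, sy = 4 * half_az, th = pi, off = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (is.null(fit)) {
    return(structure(list(center_az = NA_real_, center_el = NA_real_,
                          sd_long = NA_real_, sd_short = NA_real_,
                          orientation = NA_real_, amplitude = NA_real_,
                          offset = NA_real_,
                          peak_latency_ms = strf$peak_latency_ms,
                          size = NA_real_, fit_ok = FALSE),
                     class = "receptive_field"))
  }
  p <- as.list(coef(fit))
  if (p$sx >= p$sy) {
    sd_long <- p$sx; sd_short <- p$sy; ori <- p$th
  } else {
    sd_long <- p$sy; sd_short <- p$sx; ori <- p$th + pi / 2
  }
  ori <- ori %% pi
  ok <- is.finite(sd_long) && sd_long <= half_az
  structure(list(center_az = p$x0, center_el = p$y0,
                 sd_long = sd_long, sd_short = sd_short,
                 orientation = ori, amplitude = p$A, offset = p$off,
                 peak_latency_ms = strf$peak_latency_ms,
                 size = sd_long + sd_short, fit_ok = ok),
            class = "receptive_field")
}

#' @export
print.receptive_field <- function(x, ...) {
  cat(sprintf(
    "RF: center (%.1f, %.1f) deg, size %.1f deg, latency %.0f ms%s\n",
    x$center_az, x$center_el, x$size, x$peak_latency_ms,
    if (isTRUE(x$fit_ok)) "" else " [fit failed]"))
  invisible(x)
}

#' Peak z-score of an STRF against a shuffled-trace null
#'
#' Significance check for a receptive-field estimate: the spatial energy of
#' the peak-latency frame is compared with the energies obtained when the
#' per-frame response weights are circularly shifted by random offsets,
#' which preserves the weight distribution but destroys the stimulus-response
#' alignment.
#'
#' @param trace,stimulus as in [reverse_correlate()].
#' @param strf the fitted `strf` for this trace.
#' @param n_shuffle number of shifted surrogates (default 100).
#' @param seed integer seed.
#' @return z-score of the observed peak energy under the null.
#' @export
rf_peak_zscore <- function(trace, stimulus, strf, n_shuffle = 100L,
                           seed = 1L) {
  stopifnot(inherits(stimulus, "stimulus_ensemble"), inherits(strf, "strf"))
  n_frames <- dim(stimulus$frames)[3L]
  ny <- dim(stimulus$frames)[1L]; nx <- dim(stimulus$frames)[2L]
  S <- matrix(stimulus$frames, nrow = ny * nx, ncol = n_frames)
  mu <- rowMeans(S)
  l <- strf$peak_bin - 1L
  fmap <- pmin(floor((seq_along(trace) - 1) * strf$bin_s * stimulus$rate) + 1,
               n_frames)
  tt <- (l + 1L):length(trace)
  w <- frame_weights(trace[tt], fmap[tt - l], n_frames)
  w_tot <- sum(trace[tt])
  e_obs <- sum(((as.numeric(S %*% w) - mu * w_tot) / w_tot)^2)
  e_null <- with_seed(derive_seed(seed, "rf_zscore"), {
    vapply(seq_len(n_shuffle), function(s) {
      ws <- w[((seq_len(n_frames) - 1L + sample.int(n_frames - 1L, 1L)) %%
                 n_frames) + 1L]
      sum(((as.numeric(S %*% ws) - mu * w_tot) / w_tot)^2)
    }, numeric(1L))
  })
  (e_obs - mean(e_null)) / sd(e_null)
}

#' Screen filter: drop off-screen / border receptive fields
#'
#' Implements the inclusion rule of the tiling analysis: cells whose RF
#' center falls in the outermost ring of stimulus fields or off the screen
#' are eliminated, and a recording with fewer than `min_cells` surviving
#' cells is excluded altogether.
#'
#' @param rfs a data.frame with columns `roi_id`, `az`, `el` (and optionally
#'   `fit_ok`), e.g. from [rf_table()].
#' @param stimulus a `stimulus_ensemble` defining the field grid.
#' @param min_cells minimum surviving cells for the recording to be usable
#'   (default 10).
#' @return list with `kept` (roi ids), `dropped` (roi ids),
#'   `recording_excluded` (logical), `n_kept`.
#' @export
screen_filter <- function(rfs, stimulus, min_cells = 10L) {
  stopifnot(is.data.frame(rfs), inherits(stimulus, "stimulus_ensemble"))
  nx <- length(stimulus$az); ny <- length(stimulus$el)
  if (nrow(rfs) == 0L)
    return(list(kept = character(0L), dropped = character(0L),
                recording_excluded = TRUE, n_kept = 0L))
  col <- floor((rfs$az - (min(stimulus$az) - stimulus$field_w / 2)) /
                 stimulus$field_w) + 1
  row <- floor((rfs$el - (min(stimulus$el) - stimulus$field_h / 2)) /
                 stimulus$field_h) + 1
  interior <- col > 1 & col < nx & row > 1 & row < ny &
    is.finite(rfs$az) & is.finite(rfs$el)
  if ("fit_ok" %in% names(rfs)) interior <- interior & rfs$fit_ok
  kept <- as.character(rfs$roi_id[interior])
  list(kept = kept,
       dropped = as.character(rfs$roi_id[!interior]),
       recording_excluded = length(kept) < min_cells,
       n_kept = length(kept))
}

#' Collect fitted receptive fields into a table
#'
#' @param rfs list of `receptive_field` objects.
#' @param roi_ids labels (default sequential).
#' @return data.frame with columns `roi_id, az, el, sd_long, sd_short,
#'   theta, latency_ms, size, fit_ok`.
#' @export
rf_table <- function(rfs, roi_ids = seq_along(rfs)) {
  stopifnot(length(rfs) == length(roi_ids))
  data.frame(
    roi_id = as.character(roi_ids),
    az = vapply(rfs, function(r) r$center_az, numeric(1L)),
    el = vapply(rfs, function(r) r$center_el, numeric(1L)),
    sd_long = vapply(rfs, function(r) r$sd_long, numeric(1L)),
    sd_short = vapply(rfs, function(r) r$sd_short, numeric(1L)),
    theta = vapply(rfs, function(r) r$orientation, numeric(1L)),
    latency_ms = vapply(rfs, function(r) r$peak_latency_ms, numeric(1L)),
    size = vapply(rfs, function(r) r$size, numeric(1L)),
    fit_ok = vapply(rfs, function(r) isTRUE(r$fit_ok), logical(1L)),
    stringsAsFactors = FALSE)
}

#' Write / read an RF table as CSV
#'
#' @param rfs data.frame as returned by [rf_table()].
#' @param path file path.
#' @return `read_rf_csv` returns the data.frame; `write_rf_csv` returns
#'   `path` invisibly.
#' @export
write_rf_csv <- function(rfs, path) {
  write.csv(rfs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rf_csv
#' @export
read_rf_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "az", "el", "sd_long", "sd_short", "theta",
            "latency_ms", "size")
  if (!all(need %in% names(df)))
    stop("malformed RF CSV '", path, "': need columns ",
         paste(need, collapse = ", "))
  df$roi_id <- as.character(df$roi_id)
  df
}
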