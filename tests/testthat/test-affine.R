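test_that("an exact affine relation is recovered with zero deviation", {
  src <- random_pattern(15, seed = 4, unit = "deg", space = "visual",
                        scale = 30)
  A <- matrix(c(1.4, 0.3, -0.2, 1.1), 2, 2)
  b <- c(50, -20)
  xy <- as.matrix(src[, c("x", "y")]) %*% t(A)
  dst <- tiling_pattern(src$id, xy[, 1] + b[1], xy[, 2] + b[2],
                        unit = "um", space = "sc")
  fit <- affine_fit(src, dst)
  expect_equal(max(fit$deviations), 0, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients[, c("x", "y")]), A, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients[, "intercept"]), b, tolerance = 1e-9)
})

test_that("residual vectors sum to zero and the summary is isometry-invariant", {
  src <- random_pattern(25, seed = 8, unit = "deg", space = "visual")
  dst <- tiling_pattern(src$id, src$x * 10 + rnorm(25, sd = 5),
                        src$y * 10 + rnorm(25, sd = 5),
                        unit = "um", space = "sc")
  fit <- affine_fit(src, dst)
  resid <- cbind(fit$predicted$x - dst$x, fit$predicted$y - dst$y)
  expect_equal(colSums(resid), c(0, 0), tolerance = 1e-9)
  # rigid motion of dst leaves the deviation summary unchanged
  rot <- similarity_transform(dst, angle = 1.2, scale = 1, shift = c(40, -9))
  expect_equal(affine_fit(src, rot)$summary, fit$summary, tolerance = 1e-9)
  # collinear source is rank-deficient
  line <- tiling_pattern(1:5, 1:5, 2 * (1:5), unit = "deg", space = "visual")
  expect_error(affine_fit(line, line), "collinear")
})

test_that("deviation summaries use median and raw MAD", {
  expect_equal(deviation_summary(c(0, 0, 0)), c(median = 0, mad = 0))
  expect_equal(deviation_summary(c(1, 2, 3, 4, 100)), c(median = 3, mad = 1))
  set.seed(1)
  r <- sqrt(rnorm(1e4)^2 + rnorm(1e4)^2)  # Rayleigh(1)
  expect_lt(abs(deviation_summary(r)["median"] - sqrt(2 * log(2))) /
              sqrt(2 * log(2)), 0.02)
  expect_error(deviation_summary(numeric(0)), "no deviations")
})

test_that("isotropic Gaussian displacement yields the Rayleigh-median deviation", {
  # dst = src + N(0, sigma^2) per axis; the affine fit absorbs 3 of n
  # degrees of freedom per axis, so deviations are Rayleigh with
  # sigma * sqrt(1 - 3/n); the median follows the closed form
  n <- 25; sigma <- 27
  meds <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    src <- tiling_pattern(1:n, runif(n, 0, 18), runif(n, 0, 18),
                          unit = "deg", space = "visual")
    dst <- tiling_pattern(src$id,
                          src$x * (100 / 7.2) + rnorm(n, sd = sigma),
                          src$y * (100 / 7.2) + rnorm(n, sd = sigma),
                          unit = "um", space = "sc")
    unname(affine_fit(src, dst)$summary["median"])
  }, numeric(1))
  want <- sigma * sqrt(1 - 3 / n) * sqrt(2 * log(2))
  expect_lt(abs(mean(meds) - want) / want, 0.10)
})
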