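#' Affine-optimal retinotopy fit and deviation
#'
#' Finds the 6-parameter affine transformation that best maps one tiling
#' pattern onto its corresponding pattern in the other space (ordinary least
#' squares on both target coordinates jointly). The transformed source is
#' the "retinotopically ideal" pattern; the Euclidean residuals
#' \eqn{\Delta_i} measure how far each observed point deviates from perfect
#' (linear) retinotopy, in the units of the destination space.
#'
#' @param src,dst `tiling_pattern`s with identical id sets; `src` is mapped
#'   onto `dst`. At least 3 non-collinear source points.
#' @return an `affine_fit`: list with `coefficients` (2 x 3 matrix `[A | b]`
#'   so that `dst ~ A %*% src + b`), `deviations` (named vector of
#'   \eqn{\Delta_i}, `dst` units), `predicted` (ideal pattern), `summary`
#'   (median and MAD of the deviations).
#' @export
affine_fit <- function(src, dst) {
  stopifnot(inherits(src, "tiling_pattern"), inherits(dst, "tiling_pattern"))
  if (!setequal(src$id, dst$id))
    stop("patterns must share an identical id set (paired by id)")
  dst <- dst[match(src$id, dst$id), ]
  n <- nrow(src)
  if (n < 3L) stop("need at least 3 paired points")
  X <- cbind(1, src$x, src$y)
  if (qr(X)$rank < 3L)
    stop("source points are collinear; affine map is rank-deficient")
  Y <- cbind(dst$x, dst$y)
  fit <- lm.fit(X, Y)
  pred <- X %*% fit$coefficients
  dev <- sqrt(rowSums((pred - Y)^2))
  names(dev) <- src$id
  coef <- t(fit$coefficients)          # 2 x 3, rows (x', y')
  colnames(coef) <- c("intercept", "x", "y")
  rownames(coef) <- c("x", "y")
  ideal <- tiling_pattern(src$id, pred[, 1L], pred[, 2L],
                          unit = pattern_unit(dst), space = pattern_space(dst))
  structure(list(
    coefficients = coef,
    deviations = dev,
    predicted = ideal,
    summary = deviation_summary(dev)
  ), class = "affine_fit")
}

#' @export
print.affine_fit <- function(x, ...) {
  cat(sprintf("affine fit: n = %d, deviation = %.3g +/- %.3g (median +/- MAD)\n",
              length(x$deviations), x$summary["median"], x$summary["mad"]))
  invisible(x)
}

#' Median +/- MAD summary of deviations
#'
#' Robust summary used throughout: the median and the raw median absolute
#' deviation (no consistency scaling) of the per-point deviations.
#'
#' @param deviations numeric vector of nonnegative deviations, or an
#'   `affine_fit`.
#' @return named numeric vector `c(median = ..., mad = ...)`.
#' @export
deviation_summary <- function(deviations) {
  if (inherits(deviations, "affine_fit")) deviations <- deviations$deviations
  deviations <- as.numeric(deviations)
  if (length(deviations) == 0L) stop("no deviations to summarize")
  c(median = median(deviations), mad = mad(deviations, constant = 1))
}
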