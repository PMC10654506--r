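#' Overlap fraction of 1-SD receptive-field ellipses
#'
#' The fraction of visual field covered by more than one receptive field:
#' area of the union of all pairwise intersections divided by the area of
#' the union of all ellipses, each ellipse being the 1-SD contour of a
#' fitted Gaussian RF. Areas are computed on a rasterized grid.
#'
#' @param rfs data.frame with columns `az`, `el`, `sd_long`, `sd_short`,
#'   `theta` (>= 2 rows), e.g. from [rf_table()].
#' @param cell raster cell size, degrees (default 0.2; < 1% area error at
#'   typical RF scales).
#' @return overlap fraction in `[0, 1]`.
#' @export
ellipse_overlap_fraction <- function(rfs, cell = 0.2) {
  stopifnot(is.data.frame(rfs))
  if (nrow(rfs) < 2L) stop("need at least 2 RFs to compute overlap")
  pad <- max(rfs$sd_long)
  xs <- seq(min(rfs$az) - pad - cell, max(rfs$az) + pad + cell, by = cell)
  ys <- seq(min(rfs$el) - pad - cell, max(rfs$el) + pad + cell, by = cell)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  cover <- integer(length(gx))
  for (i in seq_len(nrow(rfs))) {
    th <- rfs$theta[i]
    u <- cos(th) * (gx - rfs$az[i]) + sin(th) * (gy - rfs$el[i])
    v <- -sin(th) * (gx - rfs$az[i]) + cos(th) * (gy - rfs$el[i])
    cover <- cover + ((u / rfs$sd_long[i])^2 + (v / rfs$sd_short[i])^2 <= 1)
  }
  n_union <- sum(cover >= 1L)
  if (n_union == 0L) return(0)
  sum(cover >= 2L) / n_union
}

#' Geometry of a binary ROI footprint
#'
#' Area, equivalent-circle radius and binary centroid of a segmented patch
#' mask, assuming square pixels. The radius convention is
#' `sqrt(area / pi)`, i.e. the radius of the circle with the patch's area.
#'
#' @param mask logical (or 0/1) matrix; rows index y, columns x.
#' @param pixel_size pixel edge length, um (default 1.3).
#' @return list with `area` (um^2), `radius` (um), `centroid` (x, y in um,
#'   pixel centers), `n_pixels`.
#' @export
patch_geometry <- function(mask, pixel_size = 1.3) {
  mask <- as.matrix(mask) > 0
  if (!any(mask)) stop("empty mask")
  n <- sum(mask)
  area <- n * pixel_size^2
  idx <- which(mask, arr.ind = TRUE)
  list(area = area,
       radius = sqrt(area / pi),
       centroid = c(x = mean(idx[, 2L] - 0.5) * pixel_size,
                    y = mean(idx[, 1L] - 0.5) * pixel_size),
       n_pixels = n)
}

#' Pairwise overlap fraction of binary footprints
#'
#' Same definition as [ellipse_overlap_fraction()] on pixel masks: pixels
#' covered by at least two patches over pixels covered by at least one.
#'
#' @param masks list of logical matrices of identical dimensions.
#' @return overlap fraction in `[0, 1]`.
#' @export
pairwise_patch_overlap <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 2L)
  dims <- unique(lapply(masks, dim))
  if (length(dims) != 1L) stop("all masks must share the same dimensions")
  cover <- Reduce(`+`, lapply(masks, function(m) (as.matrix(m) > 0) * 1L))
  n_union <- sum(cover >= 1L)
  if (n_union == 0L) return(0)
  sum(cover >= 2L) / n_union
}

#' Outlier-trimmed Pearson correlation between RF size and patch size
#'
#' Pairs in which either variable falls outside its central 95% range
#' (2.5-97.5 percentiles) are dropped as outliers before computing the
#' Pearson correlation with a two-sided test.
#'
#' @param sizes_rf RF sizes, degrees.
#' @param sizes_patch patch sizes, um (paired with `sizes_rf`).
#' @return list with `r`, `p`, `n_used`, `n_dropped`.
#' @export
rf_patch_size_correlation <- function(sizes_rf, sizes_patch) {
  if (length(sizes_rf) != length(sizes_patch))
    stop("sizes_rf and sizes_patch must be paired (equal length)")
  ok <- is.finite(sizes_rf) & is.finite(sizes_patch)
  sizes_rf <- sizes_rf[ok]; sizes_patch <- sizes_patch[ok]
  q1 <- quantile(sizes_rf, c(0.025, 0.975), names = FALSE)
  q2 <- quantile(sizes_patch, c(0.025, 0.975), names = FALSE)
  keep <- sizes_rf >= q1[1L] & sizes_rf <= q1[2L] &
          sizes_patch >= q2[1L] & sizes_patch <= q2[2L]
  if (sum(keep) < 3L)
    stop("fewer than 3 pairs remain after the 95% interval trim")
  ct <- cor.test(sizes_rf[keep], sizes_patch[keep], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       n_used = sum(keep), n_dropped = sum(!keep))
}
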