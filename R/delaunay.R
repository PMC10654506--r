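#' Delaunay triangulation of a tiling pattern
#'
#' Computes the Delaunay triangulation of the pattern's points under the
#' Euclidean metric. Its edge set defines the spatial adjacency relation the
#' tiling-match statistic compares across coordinate spaces. Cocircular
#' degeneracies (e.g. four points on a square) are resolved deterministically
#' by the fixed index-ordered point insertion of the incremental algorithm,
#' so repeated runs return identical edge sets.
#'
#' @param pattern a `tiling_pattern` with at least 3 non-collinear points.
#' @return a `delaunay_triangulation`: list with `edges` (2-column character
#'   matrix of id pairs, each row sorted, rows ordered), `triangles`
#'   (3-column character matrix of id triples), `ids`, and `n`.
#' @export
delaunay <- function(pattern) {
  stopifnot(inherits(pattern, "tiling_pattern"))
  if (nrow(pattern) < 3L)
    stop("need at least 3 points to triangulate")
  tri_idx <- delaunay_triangles_cpp(pattern$x, pattern$y)
  n <- nrow(pattern)
  i <- c(tri_idx[, 1L], tri_idx[, 2L], tri_idx[, 1L])
  j <- c(tri_idx[, 2L], tri_idx[, 3L], tri_idx[, 3L])
  code <- sort(unique((pmin(i, j) - 1) * n + pmax(i, j)))
  edges_idx <- cbind((code - 1) %/% n + 1L, (code - 1L) %% n + 1L)
  ids <- pattern$id
  structure(list(
    edges = cbind(ids[edges_idx[, 1L]], ids[edges_idx[, 2L]]),
    triangles = cbind(ids[tri_idx[, 1L]], ids[tri_idx[, 2L]],
                      ids[tri_idx[, 3L]]),
    ids = ids,
    n = nrow(pattern)
  ), class = "delaunay_triangulation")
}

#' @export
print.delaunay_triangulation <- function(x, ...) {
  cat(sprintf("Delaunay triangulation: %d points, %d edges, %d triangles\n",
              x$n, nrow(x$edges), nrow(x$triangles)))
  invisible(x)
}

# canonical "i|j" string keys for unordered id pairs
edge_keys <- function(edges) {
  a <- pmin(edges[, 1L], edges[, 2L])
  b <- pmax(edges[, 1L], edges[, 2L])
  paste(a, b, sep = "|")
}

#' Delaunay edge lengths
#'
#' @param pattern a `tiling_pattern`.
#' @param tri optional precomputed triangulation of `pattern`.
#' @return numeric vector of Euclidean edge lengths in the pattern's unit.
#' @export
delaunay_edge_lengths <- function(pattern, tri = delaunay(pattern)) {
  i <- match(tri$edges[, 1L], pattern$id)
  j <- match(tri$edges[, 2L], pattern$id)
  sqrt((pattern$x[i] - pattern$x[j])^2 + (pattern$y[i] - pattern$y[j])^2)
}
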