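#' Tiling-pattern match between two corresponding point sets
#'
#' The core statistic of the package. Both patterns are triangulated
#' (Delaunay, Euclidean metric, each in its own space and unit) and edges are
#' compared as unordered pairs of point *ids* — never by geometry — so the
#' statistic measures how well the adjacency structure of one space is
#' preserved in the other. The match is the number of common edges divided by
#' the mean of the two edge counts, in percent.
#'
#' @param pat_a,pat_b `tiling_pattern`s with identical id sets (points are
#'   paired by id).
#' @param ids optional subset of ids on which edges are evaluated (an edge
#'   counts only if both endpoints are in `ids`); used to exclude unstable
#'   convex-hull boundary nodes of simulated lattices.
#' @return a `match_result`: list with `fraction` (percent), `common_edges`,
#'   `unique_a`, `unique_b` (2-column id matrices), `n_edges_a`, `n_edges_b`.
#' @export
tiling_match <- function(pat_a, pat_b, ids = NULL) {
  stopifnot(inherits(pat_a, "tiling_pattern"), inherits(pat_b, "tiling_pattern"))
  if (!setequal(pat_a$id, pat_b$id))
    stop("patterns must share an identical id set (paired by id)")
  ta <- delaunay(pat_a)
  tb <- delaunay(pat_b)
  match_triangulations(ta, tb, ids = ids)
}

# match statistic from two precomputed triangulations
match_triangulations <- function(ta, tb, ids = NULL) {
  ea <- ta$edges
  eb <- tb$edges
  if (!is.null(ids)) {
    ids <- as.character(ids)
    ea <- ea[ea[, 1L] %in% ids & ea[, 2L] %in% ids, , drop = FALSE]
    eb <- eb[eb[, 1L] %in% ids & eb[, 2L] %in% ids, , drop = FALSE]
  }
  ka <- edge_keys(ea)
  kb <- edge_keys(eb)
  common <- intersect(ka, kb)
  denom <- mean(c(length(ka), length(kb)))
  structure(list(
    fraction = if (denom > 0) 100 * length(common) / denom else NA_real_,
    common_edges = ea[ka %in% common, , drop = FALSE],
    unique_a = ea[!ka %in% common, , drop = FALSE],
    unique_b = eb[!kb %in% common, , drop = FALSE],
    n_edges_a = length(ka),
    n_edges_b = length(kb)
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("tiling match: %.1f%% (%d common / %d vs %d edges)\n",
              x$fraction, nrow(x$common_edges), x$n_edges_a, x$n_edges_b))
  invisible(x)
}

#' Bootstrap chance level of the tiling match
#'
#' Null distribution of the match statistic when the correspondence between
#' the two patterns is destroyed: the id assignment of `pat_b` is randomly
#' permuted (full permutation, no replacement) and the match recomputed, for
#' `repetitions` draws. The geometry of each pattern — hence each edge set —
#' is unchanged; only the pairing is shuffled, so the null is cheap to
#' evaluate. The chance threshold is the one-sided (1 - alpha) quantile of
#' the null, matching a chance level at p = alpha.
#'
#' @inheritParams tiling_match
#' @param repetitions number of permutations (default 10000; < 100 is
#'   refused as too coarse for the 95th percentile).
#' @param alpha one-sided significance level (default 0.05).
#' @param seed integer seed for the permutation stream.
#' @return a `bootstrap_null`: list with `null` (vector of null match
#'   fractions), `threshold` (percent), `alpha`, `seed`.
#' @export
bootstrap_chance <- function(pat_a, pat_b, repetitions = 10000L,
                             alpha = 0.05, seed = 1L, ids = NULL) {
  stopifnot(inherits(pat_a, "tiling_pattern"), inherits(pat_b, "tiling_pattern"))
  if (!setequal(pat_a$id, pat_b$id))
    stop("patterns must share an identical id set (paired by id)")
  repetitions <- as.integer(repetitions)
  if (repetitions < 100L)
    stop("repetitions must be >= 100 for a stable chance threshold")
  ta <- delaunay(pat_a)
  tb <- delaunay(pat_b)

  all_ids <- sort(pat_a$id)
  ia <- matrix(match(ta$edges, all_ids), ncol = 2L)
  ib <- matrix(match(tb$edges, all_ids), ncol = 2L)
  keep_idx <- if (is.null(ids)) NULL else which(all_ids %in% as.character(ids))
  n <- length(all_ids)

  code <- function(e) {
    a <- pmin(e[, 1L], e[, 2L]); b <- pmax(e[, 1L], e[, 2L])
    (a - 1) * n + b
  }
  restrict <- function(e) {
    if (is.null(keep_idx)) e
    else e[e[, 1L] %in% keep_idx & e[, 2L] %in% keep_idx, , drop = FALSE]
  }
  ca <- code(restrict(ia))
  null <- with_seed(derive_seed(seed, "bootstrap_chance"), {
    vapply(seq_len(repetitions), function(r) {
      perm <- sample.int(n)
      eb <- matrix(perm[ib], ncol = 2L)
      cb <- code(restrict(eb))
      denom <- mean(c(length(ca), length(cb)))
      if (denom > 0) 100 * length(intersect(ca, cb)) / denom else NA_real_
    }, numeric(1L))
  })
  structure(list(
    null = null,
    threshold = as.numeric(quantile(null, 1 - alpha, names = FALSE)),
    alpha = alpha,
    seed = seed
  ), class = "bootstrap_null")
}

#' @export
print.bootstrap_null <- function(x, ...) {
  cat(sprintf(
    "bootstrap chance level: %.1f%% at p = %.2f (%d permutations)\n",
    x$threshold, x$alpha, length(x$null)))
  invisible(x)
}
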