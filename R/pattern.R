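#' Construct a tiling pattern (labeled 2D point set)
#'
#' A tiling pattern is the basic container of the package: a set of labeled
#' points in one coordinate space — either superior colliculus tissue
#' coordinates (micrometers) or visual space (degrees). Corresponding points
#' in two spaces (an axon patch and its receptive field, say) carry the same
#' id, which is how all downstream comparisons pair them.
#'
#' @param ids vector of unique point labels (coerced to character).
#' @param x,y numeric coordinates, finite.
#' @param unit `"um"` or `"deg"`.
#' @param space `"sc"` (collicular tissue) or `"visual"`.
#' @return a `tiling_pattern`: a data.frame with columns `id`, `x`, `y` and
#'   attributes `unit` and `space`.
#' @export
tiling_pattern <- function(ids, x, y, unit = c("um", "deg"),
                           space = c("sc", "visual")) {
  unit <- match.arg(unit)
  space <- match.arg(space)
  ids <- as.character(ids)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(ids) != length(x) || length(x) != length(y))
    stop("ids, x and y must have equal length")
  if (anyDuplicated(ids)) stop("point ids must be unique")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("all coordinates must be finite")
  out <- data.frame(id = ids, x = x, y = y, stringsAsFactors = FALSE)
  attr(out, "unit") <- unit
  attr(out, "space") <- space
  class(out) <- c("tiling_pattern", "data.frame")
  out
}

#' @export
print.tiling_pattern <- function(x, ...) {
  cat(sprintf("tiling pattern: %d points [%s, %s space]\n",
              nrow(x), attr(x, "unit"), attr(x, "space")))
  print(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more\n", nrow(x) - 6))
  invisible(x)
}

pattern_unit <- function(p) attr(p, "unit")
pattern_space <- function(p) attr(p, "space")

as_xy <- function(p) cbind(p$x, p$y)

#' Interior ids of a lattice-derived pattern
#'
#' Delaunay edges touching the convex-hull boundary are unstable under small
#' perturbations, so match statistics on simulated lattices are evaluated on
#' interior nodes only. For a pattern generated by [make_hex_lattice()] this
#' returns the ids with at least `margin` full rows/columns of lattice
#' neighbors on every side.
#'
#' @param pattern a `tiling_pattern` carrying a `grid` attribute
#'   (as produced by [make_hex_lattice()]).
#' @param margin number of boundary rows/columns to drop (default 1).
#' @return character vector of interior ids.
#' @export
interior_ids <- function(pattern, margin = 1L) {
  g <- attr(pattern, "grid")
  if (is.null(g)) stop("pattern carries no lattice grid information")
  keep <- g$row > margin & g$row <= g$rows - margin &
          g$col > margin & g$col <= g$cols - margin
  pattern$id[keep]
}

#' Read / write tiling patterns as CSV
#'
#' The on-disk format is a plain CSV with columns `id, x, y, unit, space`
#' (`unit` in `um`/`deg`, `space` in `sc`/`visual`, constant per file).
#' Round-trips are exact to double precision.
#'
#' @param pattern a `tiling_pattern`.
#' @param path file path.
#' @return `read_pattern_csv` returns a `tiling_pattern`;
#'   `write_pattern_csv` returns `path` invisibly.
#' @export
write_pattern_csv <- function(pattern, path) {
  stopifnot(inherits(pattern, "tiling_pattern"))
  df <- data.frame(id = pattern$id, x = pattern$x, y = pattern$y,
                   unit = pattern_unit(pattern), space = pattern_space(pattern))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pattern_csv
#' @export
read_pattern_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y", "unit", "space")
  if (!all(need %in% names(df)))
    stop("malformed pattern CSV '", path, "': need columns ",
         paste(need, collapse = ", "))
  bad <- which(!is.finite(df$x) | !is.finite(df$y))
  if (length(bad))
    stop("non-finite coordinates in '", path, "' at data line(s) ",
         paste(bad, collapse = ", "))
  unit <- unique(df$unit)
  space <- unique(df$space)
  if (length(unit) != 1L || !unit %in% c("um", "deg"))
    stop("unknown unit tag in '", path, "'; allowed units: um, deg")
  if (length(space) != 1L || !space %in% c("sc", "visual"))
    stop("unknown space tag in '", path, "'; allowed spaces: sc, visual")
  tiling_pattern(df$id, df$x, df$y, unit = unit, space = space)
}
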