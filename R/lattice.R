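#' Jittered hexagonal lattice generator
#'
#' Simulates the tiling pattern of a cell mosaic as a 2D hexagonal
#' (triangular-packing) lattice with additive isotropic Gaussian jitter. The
#' jitter SD is expressed as a fraction of the lattice spacing and is applied
#' independently per axis; 10% of the spacing reproduces the dense, regular
#' packing of retinal ganglion cell somata. The lattice is centered on the
#' origin so patterns of different spacings share a common frame.
#'
#' @param spacing lattice constant (nearest-neighbor distance), in the
#'   pattern's unit; must be > 0.
#' @param jitter_frac jitter SD as a fraction of `spacing` (>= 0).
#' @param rows,cols lattice dimensions (>= 2).
#' @param seed integer seed; same seed gives an identical pattern.
#' @param unit,space coordinate tags, as in [tiling_pattern()].
#' @return a `tiling_pattern` of `rows * cols` points whose `grid` attribute
#'   records the row/column of each node (used by [interior_ids()]).
#' @export
make_hex_lattice <- function(spacing, jitter_frac = 0.1, rows = 9L, cols = 9L,
                             seed = 1L, unit = c("um", "deg"),
                             space = c("sc", "visual")) {
  unit <- match.arg(unit)
  space <- match.arg(space)
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a single positive number")
  if (jitter_frac < 0) stop("jitter_frac must be >= 0")
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 2L || cols < 2L) stop("rows and cols must be >= 2")

  row <- rep(seq_len(rows), each = cols)
  col <- rep(seq_len(cols), times = rows)
  # triangular packing: rows spacing * sqrt(3)/2 apart, odd rows offset by L/2
  x <- (col - 1) * spacing + ((row - 1) %% 2) * spacing / 2
  y <- (row - 1) * spacing * sqrt(3) / 2
  x <- x - mean(x)
  y <- y - mean(y)
  if (jitter_frac > 0) {
    n <- rows * cols
    jit <- with_seed(seed, matrix(rnorm(2L * n, sd = jitter_frac * spacing),
                                  ncol = 2L))
    x <- x + jit[, 1L]
    y <- y + jit[, 2L]
  }
  out <- tiling_pattern(seq_len(rows * cols), x, y, unit = unit, space = space)
  attr(out, "grid") <- list(rows = rows, cols = cols, row = row, col = col)
  out
}
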