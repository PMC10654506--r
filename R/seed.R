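#' Derive a deterministic child seed from a root seed and a stream name
#'
#' All stochastic stages of the pipeline draw their randomness from named
#' substreams of a single root seed, so any stage can be rerun in isolation
#' and reproduce its output exactly. The derivation is a simple polynomial
#' string hash folded with the root seed modulo 2^31 - 1; it is stable across
#' platforms and R sessions.
#'
#' @param seed integer root seed.
#' @param key character stream name (e.g. \code{"sweep_sigma"}).
#' @return a single integer in \code{[1, 2^31 - 2]} suitable for
#'   \code{set.seed()}.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  m <- 2147483647  # 2^31 - 1 (prime)
  h <- as.double(seed) %% m
  for (c in utf8ToInt(paste(key, collapse = "/"))) {
    h <- (h * 31 + c) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
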