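# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles share no code with the package internals they check.

# Brute-force Delaunay triangles by the empty-circumcircle definition:
# a triple (i, j, k) is a Delaunay triangle iff no other point lies strictly
# inside its circumcircle. Valid for point sets in general position.
bruteforce_delaunay_edges <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3)
  edges <- matrix(integer(0), ncol = 2)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12 * max(abs(c(ax, ay, bx, by, cx, cy)), 1)^2) next
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    others <- setdiff(seq_len(n), c(i, j, k))
    d2 <- (x[others] - ux)^2 + (y[others] - uy)^2
    if (all(d2 > r2 * (1 - 1e-9))) {
      edges <- rbind(edges, c(i, j), c(j, k), c(i, k))
    }
  }
  unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

# canonical sorted "i|j" keys for an edge matrix of ids or indices
oracle_edge_keys <- function(edges) {
  a <- pmin(as.character(edges[, 1]), as.character(edges[, 2]))
  b <- pmax(as.character(edges[, 1]), as.character(edges[, 2]))
  sort(paste(a, b, sep = "|"))
}

# random general-position point pattern
random_pattern <- function(n, seed, unit = "um", space = "sc", scale = 100) {
  set.seed(seed)
  tiling_pattern(seq_len(n), runif(n) * scale, runif(n) * scale,
                 unit = unit, space = space)
}

# apply a similarity transform (rotation + scale + translation) to a pattern
similarity_transform <- function(pat, angle = 0, scale = 1, shift = c(0, 0)) {
  x <- scale * (cos(angle) * pat$x - sin(angle) * pat$y) + shift[1]
  y <- scale * (sin(angle) * pat$x + cos(angle) * pat$y) + shift[2]
  out <- tiling_pattern(pat$id, x, y,
                        unit = attr(pat, "unit"), space = attr(pat, "space"))
  attr(out, "grid") <- attr(pat, "grid")
  out
}

# build an strf object holding a single rendered frame, for direct fits
frame_strf <- function(frame, az, el, peak_latency_ms = 100) {
  structure(list(rf = array(frame, dim = c(dim(frame), 1L)),
                 az = az, el = el, energy = sum(frame^2), peak_bin = 1L,
                 peak_latency_ms = peak_latency_ms,
                 bin_s = 1 / 60, window_s = 0.5, total_weight = 1),
            class = "strf")
}

# render a noise-free elliptical Gaussian on a stimulus-like field grid
render_gaussian_frame <- function(az, el, x0, y0, sd_long, sd_short,
                                  theta = 0, amp = 1, offset = 0) {
  grid <- expand.grid(el = el, az = az)
  u <- cos(theta) * (grid$az - x0) + sin(theta) * (grid$el - y0)
  v <- -sin(theta) * (grid$az - x0) + cos(theta) * (grid$el - y0)
  matrix(offset + amp * exp(-0.5 * ((u / sd_long)^2 + (v / sd_short)^2)),
         nrow = length(el))
}
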