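#' Generative model configuration
#'
#' Bundles all parameters of the retinocollicular lattice model. Defaults are
#' the experimentally measured scales: receptive-field (RF) mosaic spacing
#' 7.2 degrees, axon patch spacing 100 um, SC soma spacing 56 um, base
#' lattice jitter 10% of the spacing, SC dendritic field radius 200 um, RGC
#' axonal field diameter 135 um. `sigma` (axonal projection jitter SD, um)
#' and `lambda_mean` (mean RGC inputs per SC neuron) are the two free
#' parameters the inference module estimates.
#'
#' @param L_rf RF lattice spacing, degrees.
#' @param L_axon axon lattice spacing, um.
#' @param L_soma SC soma lattice spacing, um.
#' @param jitter_frac base-lattice jitter SD as a fraction of spacing.
#' @param sigma axonal projection jitter SD, um (>= 0).
#' @param lambda_mean mean of the Poisson input convergence (>= 1 when the
#'   convergence step is simulated).
#' @param dend_radius SC dendritic field radius, um.
#' @param axon_field_diam RGC axonal field diameter, um.
#' @param grid_rows,grid_cols lattice dimensions.
#' @param margin_rows,margin_cols boundary rows/columns excluded from match
#'   evaluation.
#' @param seed root RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(L_rf = 7.2, L_axon = 100, L_soma = 56,
                       jitter_frac = 0.1, sigma = 27, lambda_mean = 5.5,
                       dend_radius = 200, axon_field_diam = 135,
                       grid_rows = 9L, grid_cols = 9L,
                       margin_rows = 1L, margin_cols = 1L, seed = 1L) {
  cfg <- list(L_rf = L_rf, L_axon = L_axon, L_soma = L_soma,
              jitter_frac = jitter_frac, sigma = sigma,
              lambda_mean = lambda_mean, dend_radius = dend_radius,
              axon_field_diam = axon_field_diam,
              grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols),
              margin_rows = as.integer(margin_rows),
              margin_cols = as.integer(margin_cols),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (L_rf <= 0 || L_axon <= 0 || L_soma <= 0)
      stop("all lattice spacings must be > 0")
    if (jitter_frac < 0) stop("jitter_frac must be >= 0")
    if (sigma < 0) stop("sigma must be >= 0")
    if (lambda_mean < 1) stop("lambda_mean must be >= 1")
    if (dend_radius <= 0 || axon_field_diam <= 0)
      stop("dend_radius and axon_field_diam must be > 0")
    if (grid_rows < 2L || grid_cols < 2L) stop("grid must be at least 2 x 2")
  })
  invisible(cfg)
}

#' Project a receptive-field mosaic into collicular coordinates
#'
#' Step 2 of the generative model. The RF pattern (degrees) is mapped into
#' tissue coordinates by the uniform isotropic scaling `L_axon / L_rf`
#' (um per degree) — the retinotopically perfect projection — and each axon
#' terminal is then displaced by i.i.d. Gaussian noise `N[0, sigma^2]` per
#' axis. `sigma = 0` therefore yields perfect retinotopy (100% tiling match
#' with the RF pattern). Point ids are preserved.
#'
#' @param rf_pattern `tiling_pattern` in degrees (visual space).
#' @param L_axon target axon lattice spacing, um.
#' @param L_rf RF lattice spacing, degrees (scale reference).
#' @param sigma projection jitter SD, um (>= 0).
#' @param seed integer seed.
#' @return a `tiling_pattern` in um (sc space), same ids; the lattice `grid`
#'   attribute of `rf_pattern`, if present, is carried over.
#' @export
project_axons <- function(rf_pattern, L_axon = 100, L_rf = 7.2, sigma = 0,
                          seed = 1L) {
  stopifnot(inherits(rf_pattern, "tiling_pattern"))
  if (nrow(rf_pattern) == 0L) stop("rf_pattern is empty")
  if (pattern_unit(rf_pattern) != "deg")
    stop("rf_pattern must be in degrees (visual space)")
  if (sigma < 0) stop("sigma must be >= 0")
  s <- L_axon / L_rf
  x <- rf_pattern$x * s
  y <- rf_pattern$y * s
  if (sigma > 0) {
    n <- nrow(rf_pattern)
    noise <- with_seed(seed, matrix(rnorm(2L * n, sd = sigma), ncol = 2L))
    x <- x + noise[, 1L]
    y <- y + noise[, 2L]
  }
  out <- tiling_pattern(rf_pattern$id, x, y, unit = "um", space = "sc")
  attr(out, "grid") <- attr(rf_pattern, "grid")
  out
}

#' Intersection area of two disks
#'
#' Closed-form lens area of two disks of radii `r1`, `r2` with center
#' distance `d`: 0 when disjoint (`d >= r1 + r2`), the full smaller disk when
#' nested (`d <= |r1 - r2|`), and the two circular segments otherwise. Used
#' as the connectivity weight between an SC dendritic field and an RGC
#' axonal field.
#'
#' @param r1,r2 disk radii (> 0).
#' @param d center distance (>= 0). Vectorized over `d`.
#' @return intersection area(s), in squared length units.
#' @export
circle_overlap_area <- function(r1, r2, d) {
  if (any(r1 <= 0) || any(r2 <= 0)) stop("radii must be > 0")
  if (any(d < 0)) stop("distance must be >= 0")
  n <- max(length(r1), length(r2), length(d))
  r1 <- rep_len(r1, n); r2 <- rep_len(r2, n); d <- rep_len(d, n)
  out <- numeric(n)
  nested <- d <= abs(r1 - r2)
  out[nested] <- pi * pmin(r1, r2)[nested]^2
  lens <- !nested & d < r1 + r2
  if (any(lens)) {
    rr1 <- r1[lens]; rr2 <- r2[lens]; dd <- d[lens]
    a1 <- (dd^2 + rr1^2 - rr2^2) / (2 * dd * rr1)
    a2 <- (dd^2 + rr2^2 - rr1^2) / (2 * dd * rr2)
    a1 <- pmin(pmax(a1, -1), 1)
    a2 <- pmin(pmax(a2, -1), 1)
    out[lens] <- rr1^2 * acos(a1) + rr2^2 * acos(a2) -
      0.5 * sqrt(pmax(0, (-dd + rr1 + rr2) * (dd + rr1 - rr2) *
                         (dd - rr1 + rr2) * (dd + rr1 + rr2)))
  }
  out
}

# zero-truncated Poisson draws by inverse CDF: u ~ U(P(K=0), 1), k = F^-1(u)
rztpois <- function(n, lambda) {
  u <- runif(n, min = ppois(0, lambda), max = 1)
  qpois(u, lambda)
}

#' Draw the RGC-to-SC convergence pattern
#'
#' Step 4a of the generative model. Each SC neuron receives input from `k`
#' nearest RGC axon terminals (Euclidean distance in tissue coordinates),
#' where `k` is drawn from a zero-truncated Poisson with mean parameter
#' `lambda_mean` (a neuron with zero retinal inputs has no RF and no
#' counterpart in the data). Connection weights are proportional to the
#' overlap area between the SC dendritic field (disk of radius
#' `dend_radius`) and the RGC axonal field (disk of diameter
#' `axon_field_diam`) at the soma-axon distance, renormalized to sum to 1;
#' if every overlap is zero the weights fall back to uniform.
#'
#' @param sc_soma,axon `tiling_pattern`s in um.
#' @param lambda_mean Poisson mean (>= 1).
#' @param dend_radius SC dendritic field radius, um.
#' @param axon_field_diam RGC axonal field diameter, um.
#' @param seed integer seed.
#' @return a `connectivity_set`: list of records `list(sc_id, axon_ids,
#'   weights)`, one per SC neuron.
#' @export
draw_convergence <- function(sc_soma, axon, lambda_mean = 5.5,
                             dend_radius = 200, axon_field_diam = 135,
                             seed = 1L) {
  stopifnot(inherits(sc_soma, "tiling_pattern"), inherits(axon, "tiling_pattern"))
  if (nrow(axon) == 0L) stop("axon pattern is empty")
  if (pattern_unit(sc_soma) != "um" || pattern_unit(axon) != "um")
    stop("both patterns must be in um (sc space)")
  if (lambda_mean < 1) stop("lambda_mean must be >= 1")
  n_sc <- nrow(sc_soma)
  ks <- with_seed(derive_seed(seed, "convergence"),
                  pmin(rztpois(n_sc, lambda_mean), nrow(axon)))
  ax_xy <- as_xy(axon)
  recs <- vector("list", n_sc)
  for (i in seq_len(n_sc)) {
    d <- sqrt((ax_xy[, 1L] - sc_soma$x[i])^2 + (ax_xy[, 2L] - sc_soma$y[i])^2)
    ord <- order(d, seq_along(d))          # index tie-break, deterministic
    sel <- ord[seq_len(ks[i])]
    w <- circle_overlap_area(dend_radius, axon_field_diam / 2, d[sel])
    if (sum(w) <= 0) w <- rep(1, length(sel))
    recs[[i]] <- list(sc_id = sc_soma$id[i],
                      axon_ids = axon$id[sel],
                      weights = w / sum(w))
  }
  structure(recs, class = "connectivity_set")
}

#' @export
print.connectivity_set <- function(x, ...) {
  k <- vapply(x, function(r) length(r$axon_ids), integer(1L))
  cat(sprintf("connectivity: %d SC neurons, k = %d-%d (mean %.2f)\n",
              length(x), min(k), max(k), mean(k)))
  invisible(x)
}

#' Receptive-field centers of SC neurons under a convergence pattern
#'
#' Step 4b of the generative model: the RF center of each SC neuron is the
#' connection-weighted average of the RF centers of its input RGCs.
#'
#' @param connectivity a `connectivity_set` from [draw_convergence()].
#' @param rgc_rf `tiling_pattern` of RGC RF centers (degrees); must contain
#'   every axon id referenced by `connectivity`.
#' @return a `tiling_pattern` in degrees whose ids are the SC ids.
#' @export
compute_sc_rfs <- function(connectivity, rgc_rf) {
  stopifnot(inherits(connectivity, "connectivity_set"),
            inherits(rgc_rf, "tiling_pattern"))
  idx_of <- setNames(seq_len(nrow(rgc_rf)), rgc_rf$id)
  xs <- numeric(length(connectivity))
  ys <- numeric(length(connectivity))
  ids <- character(length(connectivity))
  for (i in seq_along(connectivity)) {
    r <- connectivity[[i]]
    j <- idx_of[r$axon_ids]
    if (anyNA(j))
      stop("connectivity references axon id(s) absent from the RF pattern: ",
           paste(r$axon_ids[is.na(j)], collapse = ", "))
    xs[i] <- sum(r$weights * rgc_rf$x[j])
    ys[i] <- sum(r$weights * rgc_rf$y[j])
    ids[i] <- r$sc_id
  }
  tiling_pattern(ids, xs, ys, unit = "deg", space = "visual")
}

#' Simulate the full retinocollicular model (steps 1-4)
#'
#' Convenience wrapper generating one realization of the complete generative
#' model: (1) RGC RF mosaic as a jittered hexagonal lattice (`L_rf`,
#' degrees); (2) axonal projection into SC with jitter `sigma`
#' (`L_axon`, um); (3) SC soma mosaic as an independent jittered lattice
#' (`L_soma`, um), centered on the same origin; (4) Poisson convergence onto
#' the nearest axons with disk-overlap weights, giving each SC neuron an RF
#' center. Each step draws from a named substream of `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer root seed (defaults to `config$seed`).
#' @return a `ground_truth` list: `rgc_rf`, `axon`, `sc_soma`, `sc_rf`
#'   (tiling patterns), `connectivity`, `config`.
#' @export
simulate_retinocollicular <- function(config = sim_config(),
                                      seed = config$seed) {
  validate_sim_config(config)
  rgc_rf <- make_hex_lattice(config$L_rf, config$jitter_frac,
                             config$grid_rows, config$grid_cols,
                             seed = derive_seed(seed, "rgc_lattice"),
                             unit = "deg", space = "visual")
  axon <- project_axons(rgc_rf, L_axon = config$L_axon, L_rf = config$L_rf,
                        sigma = config$sigma,
                        seed = derive_seed(seed, "axon_jitter"))
  sc_soma <- make_hex_lattice(config$L_soma, config$jitter_frac,
                              config$grid_rows, config$grid_cols,
                              seed = derive_seed(seed, "soma_lattice"),
                              unit = "um", space = "sc")
  connectivity <- draw_convergence(sc_soma, axon,
                                   lambda_mean = config$lambda_mean,
                                   dend_radius = config$dend_radius,
                                   axon_field_diam = config$axon_field_diam,
                                   seed = seed)
  sc_rf <- compute_sc_rfs(connectivity, rgc_rf)
  attr(sc_rf, "grid") <- attr(sc_soma, "grid")
  structure(list(rgc_rf = rgc_rf, axon = axon, sc_soma = sc_soma,
                 sc_rf = sc_rf, connectivity = connectivity, config = config),
            class = "ground_truth")
}
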