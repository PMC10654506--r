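#' Sweep the projection jitter and build the match-vs-sigma curve
#'
#' Runs steps 1-2 of the generative model (RF lattice, axonal projection) at
#' each jitter level of `grid`, computes the tiling match between the RF and
#' axon patterns on the interior lattice nodes, and records the median and
#' the 2.5/97.5 percentile band over `repetitions` independent realizations.
#' The resulting monotone-decreasing curve is the forward model inverted by
#' [invert_curve()] to estimate the projection jitter from an observed match
#' level.
#'
#' @param grid jitter values to simulate, um (default 0 to 50 in 1-um steps).
#' @param repetitions realizations per grid value (>= 100).
#' @param config a [sim_config()]; `config$sigma` is overridden by the grid.
#' @param seed integer root seed.
#' @return a `sweep_result`: list with `parameter` (`"sigma"`), `grid`,
#'   `median`, `lo95`, `hi95` (percent match), `repetitions`, `direction`,
#'   `config`, `seed`.
#' @export
sweep_sigma <- function(grid = 0:50, repetitions = 1000L,
                        config = sim_config(), seed = 1L) {
  validate_sim_config(config)
  stopifnot(all(diff(grid) > 0), all(grid >= 0))
  if (any(grid > 5 * config$L_axon))
    stop("grid extends beyond 5 lattice spacings; match is pure chance there")
  repetitions <- as.integer(repetitions)
  if (repetitions < 100L) stop("repetitions must be >= 100")

  med <- lo <- hi <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    s <- grid[gi]
    fr <- vapply(seq_len(repetitions), function(r) {
      key <- sprintf("sigma/%d/%d", gi, r)
      rf <- make_hex_lattice(config$L_rf, config$jitter_frac,
                             config$grid_rows, config$grid_cols,
                             seed = derive_seed(seed, paste0(key, "/lattice")),
                             unit = "deg", space = "visual")
      ax <- project_axons(rf, L_axon = config$L_axon, L_rf = config$L_rf,
                          sigma = s,
                          seed = derive_seed(seed, paste0(key, "/jitter")))
      keep <- interior_ids(rf, margin = max(config$margin_rows,
                                            config$margin_cols))
      tiling_match(rf, ax, ids = keep)$fraction
    }, numeric(1L))
    med[gi] <- median(fr)
    q <- quantile(fr, c(0.025, 0.975), names = FALSE)
    lo[gi] <- q[1L]
    hi[gi] <- q[2L]
  }
  structure(list(parameter = "sigma", grid = as.numeric(grid), median = med,
                 lo95 = lo, hi95 = hi, repetitions = repetitions,
                 direction = "decreasing", config = config, seed = seed),
            class = "sweep_result")
}

#' Sweep the input convergence and build the match-vs-lambda curve
#'
#' Runs the full generative model (steps 1-4) at each mean convergence level
#' of `grid` with the projection jitter fixed at `sigma_fixed`, computes the
#' tiling match between the SC soma pattern and the SC RF pattern on interior
#' nodes, and records median and 95% band over `repetitions` realizations.
#' The curve increases with lambda: the more RGC inputs an SC neuron
#' averages, the closer its RF center lands to the retinotopically ideal
#' position.
#'
#' @param grid mean convergence values (default 1 to 10 in 0.25 steps).
#' @param sigma_fixed projection jitter used for step 2, um.
#' @param repetitions realizations per grid value (>= 100).
#' @param config a [sim_config()].
#' @param seed integer root seed.
#' @return a `sweep_result` with `parameter = "lambda"`.
#' @export
sweep_lambda <- function(grid = seq(1, 10, by = 0.25), sigma_fixed = 27,
                         repetitions = 1000L, config = sim_config(),
                         seed = 1L) {
  validate_sim_config(config)
  stopifnot(all(diff(grid) > 0), all(grid >= 1), sigma_fixed >= 0)
  repetitions <- as.integer(repetitions)
  if (repetitions < 100L) stop("repetitions must be >= 100")

  med <- lo <- hi <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    cfg <- config
    cfg$sigma <- sigma_fixed
    cfg$lambda_mean <- grid[gi]
    fr <- vapply(seq_len(repetitions), function(r) {
      g <- simulate_retinocollicular(
        cfg, seed = derive_seed(seed, sprintf("lambda/%d/%d", gi, r)))
      keep <- interior_ids(g$sc_soma, margin = max(cfg$margin_rows,
                                                   cfg$margin_cols))
      tiling_match(g$sc_soma, g$sc_rf, ids = keep)$fraction
    }, numeric(1L))
    med[gi] <- median(fr)
    q <- quantile(fr, c(0.025, 0.975), names = FALSE)
    lo[gi] <- q[1L]
    hi[gi] <- q[2L]
  }
  structure(list(parameter = "lambda", grid = as.numeric(grid), median = med,
                 lo95 = lo, hi95 = hi, repetitions = repetitions,
                 direction = "increasing", config = config, seed = seed),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(
    "%s sweep: %d values in [%g, %g], %d repetitions, match %0.1f-%0.1f%%\n",
    x$parameter, length(x$grid), min(x$grid), max(x$grid), x$repetitions,
    min(x$median), max(x$median)))
  invisible(x)
}

# monotone (isotonic) regression of y on x in the stated direction
monotone_curve <- function(x, y, direction) {
  if (direction == "decreasing") -isoreg(x, -y)$yf else isoreg(x, y)$yf
}

# parameter at which a monotone curve crosses `target`, linear interpolation;
# flat segments at the target level resolve to their midpoint (ties = mean)
curve_crossing <- function(x, y_mono, target, direction) {
  rng <- range(y_mono)
  if (target < rng[1L] || target > rng[2L]) return(NA_real_)
  stats::approx(y_mono, x, xout = target, ties = mean)$y
}

#' Invert a match-vs-parameter curve at an observed match level
#'
#' Estimates the generative parameter from an observed tiling match: the
#' point estimate is where the isotonic-regressed median curve crosses
#' `observed_match` (linear interpolation between grid points); the 95%
#' confidence interval is the set of parameter values whose simulated
#' 2.5-97.5% band contains the observed match, i.e. the crossings of the two
#' band curves.
#'
#' @param sweep a `sweep_result` from [sweep_sigma()] or [sweep_lambda()].
#' @param observed_match observed tiling match, percent; must lie within the
#'   range spanned by the median curve.
#' @return a `param_estimate`: list with `estimate`, `ci_lo`, `ci_hi`,
#'   `observed_match`, `parameter`.
#' @export
invert_curve <- function(sweep, observed_match) {
  stopifnot(inherits(sweep, "sweep_result"), length(observed_match) == 1L)
  dir <- sweep$direction
  med <- monotone_curve(sweep$grid, sweep$median, dir)
  if (observed_match < min(med) || observed_match > max(med))
    stop(sprintf(
      "observed match %.1f%% lies outside the median curve range [%.1f, %.1f]",
      observed_match, min(med), max(med)))
  est <- curve_crossing(sweep$grid, med, observed_match, dir)
  lo_c <- monotone_curve(sweep$grid, sweep$lo95, dir)
  hi_c <- monotone_curve(sweep$grid, sweep$hi95, dir)
  b1 <- curve_crossing(sweep$grid, lo_c, observed_match, dir)
  b2 <- curve_crossing(sweep$grid, hi_c, observed_match, dir)
  # a band curve that never reaches the observed level is clamped to the
  # grid end it saturates at
  clamp <- function(b, curve) {
    if (!is.na(b)) return(b)
    ends <- range(sweep$grid)
    if (observed_match > max(curve)) {
      if (dir == "decreasing") ends[1L] else ends[2L]
    } else {
      if (dir == "decreasing") ends[2L] else ends[1L]
    }
  }
  b1 <- clamp(b1, lo_c)
  b2 <- clamp(b2, hi_c)
  ci <- sort(c(b1, b2))
  structure(list(estimate = est, ci_lo = ci[1L], ci_hi = ci[2L],
                 observed_match = observed_match,
                 parameter = sweep$parameter),
            class = "param_estimate")
}

#' @export
print.param_estimate <- function(x, ...) {
  cat(sprintf("%s = %.2f (95%% CI %.2f-%.2f) at observed match %.1f%%\n",
              x$parameter, x$estimate, x$ci_lo, x$ci_hi, x$observed_match))
  invisible(x)
}

#' Write / read a sweep curve as CSV (param, median, lo95, hi95)
#'
#' @param sweep a `sweep_result`.
#' @param path CSV path; a JSON sidecar `<path>.json` records parameter
#'   name, repetitions, direction and seed.
#' @return `read_sweep_csv` returns a `sweep_result` (without the config
#'   snapshot); `write_sweep_csv` returns `path` invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_result"))
  write.csv(data.frame(param = sweep$grid, median = sweep$median,
                       lo95 = sweep$lo95, hi95 = sweep$hi95),
            path, row.names = FALSE, quote = FALSE)
  meta <- list(parameter = sweep$parameter, repetitions = sweep$repetitions,
               direction = sweep$direction, seed = sweep$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  df <- read.csv(path)
  need <- c("param", "median", "lo95", "hi95")
  if (!all(need %in% names(df)))
    stop("malformed sweep CSV '", path, "': need columns ",
         paste(need, collapse = ", "))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  else list(parameter = "sigma", repetitions = NA_integer_,
            direction = "decreasing", seed = NA_integer_)
  structure(list(parameter = meta$parameter, grid = df$param,
                 median = df$median, lo95 = df$lo95, hi95 = df$hi95,
                 repetitions = meta$repetitions, direction = meta$direction,
                 config = NULL, seed = meta$seed),
            class = "sweep_result")
}
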