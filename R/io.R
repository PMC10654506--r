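#' Write / read a connectivity set as JSON
#'
#' Records of `{sc_id, axon_ids[], weights[]}`, one per SC neuron.
#'
#' @param connectivity a `connectivity_set`.
#' @param path file path.
#' @return `read_connectivity_json` returns a `connectivity_set`;
#'   `write_connectivity_json` returns `path` invisibly.
#' @export
write_connectivity_json <- function(connectivity, path) {
  stopifnot(inherits(connectivity, "connectivity_set"))
  recs <- lapply(connectivity, function(r)
    list(sc_id = r$sc_id, axon_ids = as.list(r$axon_ids),
         weights = as.list(r$weights)))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_connectivity_json
#' @export
read_connectivity_json <- function(path) {
  recs <- jsonlite::read_json(path)
  out <- lapply(recs, function(r) {
    rec <- list(sc_id = as.character(r$sc_id),
                axon_ids = vapply(r$axon_ids, as.character, character(1L)),
                weights = vapply(r$weights, as.numeric, numeric(1L)))
    if (length(rec$axon_ids) < 1L)
      stop("connectivity record for '", rec$sc_id, "' has no connections")
    if (abs(sum(rec$weights) - 1) > 1e-9)
      stop("weights for '", rec$sc_id, "' do not sum to 1")
    rec
  })
  structure(out, class = "connectivity_set")
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file may set any subset of the [sim_config()] fields; unset fields
#' keep their defaults. Unknown fields are an error.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(known, collapse = ", "))
  do.call(sim_config, vals)
}

#' Run the full synthetic pipeline and write a result manifest
#'
#' End-to-end orchestration over the package's stages on simulated data:
#' `simulate` (generative model realization; pattern CSVs + connectivity
#' JSON), `tiling` (match statistics, bootstrap chance level, affine
#' deviation), and `infer` (sigma and lambda sweeps and their inversions at
#' the match levels measured on the simulated recording-scale patterns,
#' or at `observed` values supplied in `analysis`). Every output file and
#' the seeds used are listed in `manifest.json`; rerunning with the same
#' seed reproduces all outputs exactly.
#'
#' @param config a [sim_config()] (or path understood by
#'   [read_sim_config()]).
#' @param out_dir output directory (created if missing).
#' @param stages subset of `c("simulate", "tiling", "infer")`.
#' @param analysis list of analysis settings: `bootstrap_reps` (default
#'   1000), `alpha` (0.05), `sweep_reps` (default 200), `sigma_grid`,
#'   `lambda_grid`, `observed_sigma_match`, `observed_lambda_match`
#'   (defaults: the match fractions measured on the simulated patterns).
#' @param seed root seed (default `config$seed`).
#' @return the manifest, invisibly (list of outputs, seeds, settings).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = "retinotile_run",
                         stages = c("simulate", "tiling", "infer"),
                         analysis = list(), seed = NULL) {
  if (is.character(config)) config <- read_sim_config(config)
  validate_sim_config(config)
  if (is.null(seed)) seed <- config$seed
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  a <- modifyList(list(bootstrap_reps = 1000L, alpha = 0.05,
                       sweep_reps = 200L,
                       sigma_grid = 0:50,
                       lambda_grid = seq(1, 10, by = 0.25),
                       observed_sigma_match = NULL,
                       observed_lambda_match = NULL), analysis)
  manifest <- list(seed = seed, stages = stages, outputs = list(),
                   settings = a[c("bootstrap_reps", "alpha", "sweep_reps")])
  p <- function(f) file.path(out_dir, f)

  g <- simulate_retinocollicular(config, seed = derive_seed(seed, "simulate"))
  keep <- interior_ids(g$rgc_rf, margin = max(config$margin_rows,
                                              config$margin_cols))
  if ("simulate" %in% stages) {
    write_pattern_csv(g$rgc_rf, p("rgc_rf.csv"))
    write_pattern_csv(g$axon, p("axon.csv"))
    write_pattern_csv(g$sc_soma, p("sc_soma.csv"))
    write_pattern_csv(g$sc_rf, p("sc_rf.csv"))
    write_connectivity_json(g$connectivity, p("connectivity.json"))
    manifest$outputs$simulate <- c("rgc_rf.csv", "axon.csv", "sc_soma.csv",
                                   "sc_rf.csv", "connectivity.json")
  }

  axon_match <- tiling_match(g$rgc_rf, g$axon, ids = keep)$fraction
  soma_match <- tiling_match(g$sc_soma, g$sc_rf, ids = keep)$fraction
  if ("tiling" %in% stages) {
    chance <- bootstrap_chance(g$rgc_rf, g$axon,
                               repetitions = a$bootstrap_reps,
                               alpha = a$alpha,
                               seed = derive_seed(seed, "chance"))
    af <- affine_fit(g$rgc_rf, g$axon)
    res <- list(axon_match = axon_match, soma_match = soma_match,
                chance_threshold = chance$threshold, alpha = a$alpha,
                affine_deviation_median = unname(af$summary["median"]),
                affine_deviation_mad = unname(af$summary["mad"]))
    jsonlite::write_json(res, p("tiling.json"), auto_unbox = TRUE,
                         digits = NA)
    manifest$outputs$tiling <- "tiling.json"
  }

  if ("infer" %in% stages) {
    obs_s <- if (is.null(a$observed_sigma_match)) axon_match
             else a$observed_sigma_match
    sw_s <- sweep_sigma(a$sigma_grid, repetitions = a$sweep_reps,
                        config = config,
                        seed = derive_seed(seed, "sweep_sigma"))
    est_s <- invert_curve(sw_s, obs_s)
    write_sweep_csv(sw_s, p("sweep_sigma.csv"))
    obs_l <- if (is.null(a$observed_lambda_match)) soma_match
             else a$observed_lambda_match
    sw_l <- sweep_lambda(a$lambda_grid, sigma_fixed = est_s$estimate,
                         repetitions = a$sweep_reps, config = config,
                         seed = derive_seed(seed, "sweep_lambda"))
    est_l <- invert_curve(sw_l, obs_l)
    write_sweep_csv(sw_l, p("sweep_lambda.csv"))
    ests <- list(
      sigma = list(estimate = est_s$estimate, ci_lo = est_s$ci_lo,
                   ci_hi = est_s$ci_hi, observed_match = obs_s),
      lambda = list(estimate = est_l$estimate, ci_lo = est_l$ci_lo,
                    ci_hi = est_l$ci_hi, observed_match = obs_l))
    jsonlite::write_json(ests, p("estimates.json"), auto_unbox = TRUE,
                         digits = NA)
    manifest$outputs$infer <- c("sweep_sigma.csv", "sweep_lambda.csv",
                                "estimates.json")
  }

  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}

#' Write / read activity traces as CSV (roi_id, t_index, rate)
#'
#' Long-format storage of per-ROI event-rate series at the analysis bin
#' resolution; `t_index` is 1-based. Reading returns the bins x ROI matrix
#' expected by [estimate_rfs()], with ROIs ordered by first appearance.
#'
#' @param traces n_bins x n_roi numeric matrix; column names used as ROI
#'   ids (default sequential).
#' @param path file path.
#' @return `read_traces_csv` returns the matrix (ROI ids as column names);
#'   `write_traces_csv` returns `path` invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(is.matrix(traces))
  ids <- colnames(traces)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(traces)))
  df <- data.frame(
    roi_id = rep(ids, each = nrow(traces)),
    t_index = rep(seq_len(nrow(traces)), times = ncol(traces)),
    rate = as.numeric(traces))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "t_index", "rate")
  if (!all(need %in% names(df)))
    stop("malformed traces CSV '", path, "': need columns ",
         paste(need, collapse = ", "))
  ids <- unique(as.character(df$roi_id))
  n_bins <- max(df$t_index)
  out <- matrix(0, nrow = n_bins, ncol = length(ids),
                dimnames = list(NULL, ids))
  out[cbind(df$t_index, match(as.character(df$roi_id), ids))] <- df$rate
  out
}

#' Write / read binary ROI footprint masks as a multi-page TIFF
#'
#' One page per ROI; pixels are 0/1. All masks must share one image size.
#'
#' @param masks list of logical matrices.
#' @param path file path.
#' @return `read_masks_tiff` returns a list of logical matrices;
#'   `write_masks_tiff` returns `path` invisibly.
#' @export
write_masks_tiff <- function(masks, path) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  if (length(unique(lapply(masks, dim))) != 1L)
    stop("all masks must share the same dimensions")
  tiff::writeTIFF(lapply(masks, function(m) (as.matrix(m) > 0) * 1),
                  path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_masks_tiff
#' @export
read_masks_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) round(p) > 0)
}
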