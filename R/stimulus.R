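#' Random binary checkerboard stimulus ensemble
#'
#' Generates the white-noise checkerboard used for receptive-field mapping:
#' a grid of rectangular fields (3.7 deg wide, 2.9 deg high) covering a
#' screen spanning +/-36.5 deg azimuth and +/-22 deg elevation, each field
#' switched independently between black (0) and white (1) at `rate` Hz. The
#' grid holds as many whole fields as fit on the screen (19 x 15 by
#' default), centered on the origin.
#'
#' @param duration_s stimulus duration, seconds.
#' @param field_w,field_h field size, degrees.
#' @param rate update rate, Hz.
#' @param screen_az,screen_el screen half-extents, degrees.
#' @param seed integer seed.
#' @return a `stimulus_ensemble`: list with `frames` (ny x nx x n_frames
#'   array in {0,1}), field geometry, `rate`, `screen`, `az` / `el` (field
#'   center coordinates), `duration_s`, `seed`.
#' @export
checkerboard_stimulus <- function(duration_s = 600, field_w = 3.7,
                                  field_h = 2.9, rate = 4,
                                  screen_az = 36.5, screen_el = 22,
                                  seed = 1L) {
  stopifnot(duration_s > 0, field_w > 0, field_h > 0, rate > 0)
  nx <- floor(2 * screen_az / field_w)
  ny <- floor(2 * screen_el / field_h)
  n_frames <- as.integer(ceiling(duration_s * rate))
  frames <- with_seed(derive_seed(seed, "checkerboard"), {
    array(as.numeric(runif(ny * nx * n_frames) < 0.5),
          dim = c(ny, nx, n_frames))
  })
  structure(list(
    frames = frames,
    field_w = field_w, field_h = field_h, rate = rate,
    screen = list(az = screen_az, el = screen_el),
    az = (seq_len(nx) - (nx + 1) / 2) * field_w,
    el = (seq_len(ny) - (ny + 1) / 2) * field_h,
    duration_s = duration_s, seed = seed
  ), class = "stimulus_ensemble")
}

#' @export
print.stimulus_ensemble <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "checkerboard stimulus: %d x %d fields (%.1f x %.1f deg), %d frames at %g Hz\n",
    d[2L], d[1L], x$field_w, x$field_h, d[3L], x$rate))
  invisible(x)
}

#' Write / read a stimulus ensemble as a multi-page TIFF plus JSON sidecar
#'
#' One TIFF page per stimulus frame (binary, 8-bit); the sidecar records the
#' field geometry, update rate, screen extents and frame count. On read, a
#' page-count mismatch between stack and sidecar is a format error.
#'
#' @param stim a `stimulus_ensemble`.
#' @param tiff_path,json_path file paths (default sidecar: `<tiff>.json`).
#' @return `read_stimulus_tiff` returns a `stimulus_ensemble`;
#'   `write_stimulus_tiff` returns `tiff_path` invisibly.
#' @export
write_stimulus_tiff <- function(stim, tiff_path,
                                json_path = paste0(tiff_path, ".json")) {
  stopifnot(inherits(stim, "stimulus_ensemble"))
  pages <- lapply(seq_len(dim(stim$frames)[3L]),
                  function(k) stim$frames[, , k])
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 8L)
  meta <- list(field_w_deg = stim$field_w, field_h_deg = stim$field_h,
               rate_hz = stim$rate,
               screen = list(az = stim$screen$az, el = stim$screen$el),
               n_frames = dim(stim$frames)[3L],
               duration_s = stim$duration_s, seed = stim$seed)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

#' @rdname write_stimulus_tiff
#' @export
read_stimulus_tiff <- function(tiff_path,
                               json_path = paste0(tiff_path, ".json")) {
  if (!file.exists(json_path))
    stop("missing stimulus sidecar: ", json_path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (length(pages) != meta$n_frames)
    stop(sprintf("stimulus TIFF has %d pages but sidecar declares %d frames",
                 length(pages), meta$n_frames))
  frames <- array(0, dim = c(dim(pages[[1L]]), length(pages)))
  for (k in seq_along(pages)) frames[, , k] <- round(pages[[k]])
  nx <- dim(frames)[2L]; ny <- dim(frames)[1L]
  structure(list(
    frames = frames,
    field_w = meta$field_w_deg, field_h = meta$field_h_deg,
    rate = meta$rate_hz,
    screen = list(az = meta$screen$az, el = meta$screen$el),
    az = (seq_len(nx) - (nx + 1) / 2) * meta$field_w_deg,
    el = (seq_len(ny) - (ny + 1) / 2) * meta$field_h_deg,
    duration_s = meta$duration_s, seed = meta$seed
  ), class = "stimulus_ensemble")
}
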