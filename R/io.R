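#' Write a frame sequence as multi-page TIFF plus JSON sidecar
#'
#' Frames are max-normalized into `[0, 1]` for 32-bit TIFF storage; the
#' normalization scale is recorded in the sidecar
#' (`<path>.json`: `pixel_spacing_mm`, `frame_rate_hz`, `intensity_scale`,
#' optional `seed`), so [read_sequence()] restores the original intensities.
#'
#' @param x a `frame_sequence`.
#' @param path output TIFF path.
#' @param seed optional seed to record in the sidecar.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(x, path, seed = NULL) {
  stopifnot(inherits(x, "frame_sequence"))
  d <- dim(x$frames)
  scale <- max(x$frames, 1e-12)
  pages <- lapply(seq_len(d[3]), function(f) x$frames[, , f] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  sidecar <- list(pixel_spacing_mm = x$pixel_spacing_mm,
                  frame_rate_hz = x$frame_rate_hz,
                  intensity_scale = scale,
                  channel = x$channel)
  if (!is.null(seed)) sidecar$seed <- as.integer(seed)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a frame sequence written by [write_sequence()]
#'
#' @param path TIFF path; `<path>.json` must exist and contain
#'   `pixel_spacing_mm` and `frame_rate_hz`.
#' @return a `frame_sequence`.
#' @export
read_sequence <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  sc_path <- paste0(path, ".json")
  if (!file.exists(sc_path))
    abort(sprintf(
      "missing JSON sidecar %s (required keys: pixel_spacing_mm, frame_rate_hz)",
      sc_path))
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  for (key in c("pixel_spacing_mm", "frame_rate_hz"))
    if (is.null(sc[[key]]))
      abort(sprintf("sidecar %s is missing key '%s'", sc_path, key))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L)
    abort("ragged TIFF: pages have differing shapes")
  scale <- sc$intensity_scale %||% 1
  arr <- array(unlist(pages, use.names = FALSE),
               c(dims[[1]], length(pages))) * scale
  frame_sequence(arr, sc$pixel_spacing_mm, sc$frame_rate_hz,
                 sc$channel %||% NA_character_)
}

#' Pipeline configuration
#'
#' All tunable parameters of the processing chain in one validated list.
#'
#' @param keep_rank SVD rank to keep (`NULL` = automatic energy rule,
#'   see [svd_suppress_bubbles()]).
#' @param detection_k detection threshold in background SDs.
#' @param window_px centroid window (odd).
#' @param v_max gate speed, mm/s.
#' @param max_gap tracking gap frames.
#' @param min_frames minimum track length in frames.
#' @param upsampling_factor SR upsampling.
#' @param localization_uncertainty_sr_px density blur SD, SR px.
#' @param smooth_tracks apply [smooth_tracks()] after filtering (default
#'   `TRUE`).
#' @param n_isobars pressure isobar count.
#' @param block_px,search_px stage-2 registration block size / search radius.
#' @param seed master seed, forked deterministically per stage.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(keep_rank = NULL, detection_k = 4,
                            window_px = 11L, v_max = 15, max_gap = 0L,
                            min_frames = 3L, upsampling_factor = 4L,
                            localization_uncertainty_sr_px = 1,
                            smooth_tracks = TRUE,
                            n_isobars = 9L, block_px = 16L, search_px = 3L,
                            seed = 1L) {
  stopifnot(is.null(keep_rank) || keep_rank >= 1, detection_k > 0,
            window_px >= 3L, v_max > 0, max_gap >= 0L, min_frames >= 2L,
            upsampling_factor >= 1L, localization_uncertainty_sr_px >= 0,
            n_isobars >= 1L)
  structure(list(keep_rank = keep_rank, detection_k = detection_k,
                 window_px = as.integer(window_px), v_max = v_max,
                 max_gap = as.integer(max_gap),
                 min_frames = as.integer(min_frames),
                 smooth_tracks = isTRUE(smooth_tracks),
                 upsampling_factor = as.integer(upsampling_factor),
                 localization_uncertainty_sr_px =
                   localization_uncertainty_sr_px,
                 n_isobars = as.integer(n_isobars),
                 block_px = as.integer(block_px),
                 search_px = as.integer(search_px),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full processing chain on paired CEUS/B-mode sequences
#'
#' Preprocess (SVD bubble suppression on B-mode, two-stage motion estimation,
#' CEUS motion correction), localize, track, filter, build SR maps and
#' quantify, optionally writing every intermediate (motion CSV, localization
#' and track CSVs, map TIFFs, quantification JSON, provenance log) into an
#' artifact directory.
#'
#' @param ceus,bmode `frame_sequence` objects of equal frame count.
#' @param config a [pipeline_config()].
#' @param out_dir output directory for artifacts; `NULL` skips writing.
#' @param roi optional binary ROI on the SR grid.
#' @param hilum_mm,axis optional sector frame (see [quantify_testis()]).
#' @param motion_correction set `FALSE` to skip motion handling (e.g. for
#'   motion-free simulations).
#' @return list of class `ulm_result`: `motion`, `localizations`, `tracks`,
#'   `maps` (an `sr_map_set`), `quant` (a `quant_result`), `config`.
#' @export
run_pipeline <- function(ceus, bmode = NULL, config = pipeline_config(),
                         out_dir = NULL, roi = NULL, hilum_mm = NULL,
                         axis = c(1, 0), motion_correction = !is.null(bmode)) {
  stopifnot(inherits(ceus, "frame_sequence"),
            inherits(config, "pipeline_config"))
  motion <- NULL
  corrected <- ceus
  if (motion_correction) {
    if (is.null(bmode)) abort("motion correction requires a B-mode sequence")
    if (n_frames(bmode) != n_frames(ceus))
      abort("B-mode and CEUS frame counts differ")
    clean <- svd_suppress_bubbles(bmode, keep_rank = config$keep_rank)
    motion <- estimate_motion(clean, block_px = config$block_px,
                              search_px = config$search_px)
    corrected <- apply_motion_correction(ceus, motion)
  }
  loc <- detect_sequence(corrected, k = config$detection_k,
                         window_px = config$window_px)
  tracks <- link_tracks(loc, v_max = config$v_max, max_gap = config$max_gap)
  tracks <- filter_tracks(tracks, min_frames = config$min_frames)
  if (config$smooth_tracks) tracks <- smooth_tracks(tracks)
  d <- dim(corrected$frames)
  grid <- sr_grid(d[1], d[2], corrected$pixel_spacing_mm,
                  config$upsampling_factor)
  maps <- sr_map_set(tracks, grid,
                     config$localization_uncertainty_sr_px,
                     config$n_isobars)
  quant <- quantify_testis(maps, tracks, roi = roi, hilum_mm = hilum_mm,
                           axis = axis)
  res <- structure(list(motion = motion, localizations = loc,
                        tracks = tracks, maps = maps, quant = quant,
                        config = config), class = "ulm_result")
  if (!is.null(out_dir)) write_artifacts(res, corrected, out_dir)
  res
}

write_artifacts <- function(res, corrected, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(res$motion))
    utils::write.csv(tidy(res$motion),
                     file.path(out_dir, "motion.csv"), row.names = FALSE)
  utils::write.csv(as_tibble(res$localizations),
                   file.path(out_dir, "localizations.csv"),
                   row.names = FALSE)
  utils::write.csv(as_tibble(res$tracks),
                   file.path(out_dir, "tracks.csv"), row.names = FALSE)
  for (nm in c("density", "velocity_magnitude", "direction")) {
    m <- res$maps[[nm]]
    sc <- max(abs(m), 1e-12)
    tiff::writeTIFF(pmax(m, 0) / sc, file.path(out_dir,
                                               paste0(nm, ".tif")),
                    bits.per.sample = 32L, compression = "none")
  }
  q <- res$quant
  jsonlite::write_json(
    list(mean_velocity = q$mean_velocity, sd_velocity = q$sd_velocity,
         mean_tortuosity = q$mean_tortuosity,
         mean_diameter = q$mean_diameter,
         fractal_number = q$fractal_number,
         vessel_density = q$vessel_density),
    file.path(out_dir, "quant.json"), auto_unbox = TRUE, digits = NA)
  prov <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
               seed = res$config$seed,
               config = unclass(res$config),
               r_version = R.version.string)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.ulm_result <- function(x, ...) {
  cat(sprintf("<ulm_result> %d localizations, %d tracks\n",
              nrow(x$localizations), length(unique(x$tracks$track_id))))
  print(x$quant)
  invisible(x)
}
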