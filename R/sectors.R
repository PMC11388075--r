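#' Sector frame around the testicular hilum
#'
#' Defines the 12 x 30-degree regional partition used for regional analysis:
#' sectors start at the testicular long-axis direction and proceed
#' counterclockwise in physical coordinates (x to the right, y upward; image
#' rows run downward, so the raster handedness is flipped internally).
#' Sector k covers angles `[(k-1)*30, k*30)` degrees from the axis; a
#' boundary point belongs to the higher sector.
#'
#' @param hilum_mm hilum position `c(x, y)` in image mm coordinates (x
#'   lateral, y depth from the top).
#' @param axis long-axis direction `c(dx, dy_up)` in physical coordinates
#'   (need not be unit length).
#' @param n_sectors number of sectors (12).
#' @return list of class `sector_frame`.
#' @export
sector_frame <- function(hilum_mm, axis = c(1, 0), n_sectors = 12L) {
  stopifnot(length(hilum_mm) == 2L, length(axis) == 2L,
            sqrt(sum(axis^2)) > 0)
  structure(list(hilum_mm = as.numeric(hilum_mm),
                 axis = as.numeric(axis) / sqrt(sum(axis^2)),
                 n_sectors = as.integer(n_sectors),
                 sector_width_deg = 360 / n_sectors),
            class = "sector_frame")
}

#' Sector index of points relative to a sector frame
#'
#' @param x_mm,y_mm point coordinates in image mm (y = depth).
#' @param frame a [sector_frame()].
#' @return integer sector indices in `1..n_sectors`.
#' @export
sector_of <- function(x_mm, y_mm, frame) {
  dx <- x_mm - frame$hilum_mm[1]
  dy_up <- -(y_mm - frame$hilum_mm[2])  # flip: physical y is up
  theta <- atan2(dy_up, dx) - atan2(frame$axis[2], frame$axis[1])
  theta <- theta %% (2 * pi)
  width <- 2 * pi / frame$n_sectors
  idx <- floor(theta / width) + 1L
  pmin(idx, frame$n_sectors)  # guard theta == 2*pi after rounding
}

# binary sector mask on an SR grid
sector_mask <- function(frame, k, grid) {
  nr <- grid$dim[1]; nc <- grid$dim[2]
  x <- px_to_mm(matrix(seq_len(nc), nr, nc, byrow = TRUE), grid$sr_spacing_mm)
  y <- px_to_mm(matrix(seq_len(nr), nr, nc), grid$sr_spacing_mm)
  matrix(as.integer(sector_of(x, y, frame) == k), nr, nc)
}

#' Regional (12-sector) vascular metrics
#'
#' Computes the five vascular parameters per sector: the ROI is intersected
#' with each sector; density, vessel density, diameters and velocity
#' statistics are computed on the restricted rasters, and tortuosity from the
#' tracks whose midpoint falls in the sector. Sectors too small for a fractal
#' estimate report `NA`.
#'
#' @param maps an [sr_map_set()].
#' @param tracks the `mb_tracks` used to build the maps.
#' @param frame a [sector_frame()]; the hilum must lie inside the ROI.
#' @param roi optional binary ROI on the SR grid (default whole raster).
#' @return tibble with one row per sector: `sector`, `roi_px`,
#'   `mean_velocity`, `sd_velocity`, `mean_tortuosity`, `n_tracks`,
#'   `mean_diameter`, `vessel_density`, `fractal_number`.
#' @export
sector_metrics <- function(maps, tracks, frame, roi = NULL) {
  stopifnot(inherits(maps, "sr_map_set"), inherits(frame, "sector_frame"))
  grid <- maps$grid
  if (is.null(roi)) roi <- matrix(1L, grid$dim[1], grid$dim[2])
  hr <- round(sr_px(frame$hilum_mm[2], grid))
  hc <- round(sr_px(frame$hilum_mm[1], grid))
  if (hr < 1 || hr > grid$dim[1] || hc < 1 || hc > grid$dim[2] ||
      roi[hr, hc] <= 0)
    abort("hilum lies outside the ROI")

  mask <- binarize_vessels(maps$density, maps$blur_sd, roi = roi)
  skel <- centerlines(mask)
  dt2 <- if (any(skel > 0))
    2 * EBImage::distmap(mask > 0, metric = "euclidean")@.Data *
      grid$sr_spacing_mm * 1000 else NULL

  ts <- track_summary(tracks)
  mids <- dplyr::summarise(
    dplyr::group_by(as_tibble(tracks), .data$track_id),
    x_mm = mean(range(.data$x_mm)), y_mm = mean(range(.data$y_mm)),
    .groups = "drop")
  mids$sector <- sector_of(mids$x_mm, mids$y_mm, frame)
  tort <- track_tortuosity(tracks)$per_track
  tort <- dplyr::left_join(tort, mids[c("track_id", "sector")],
                           by = "track_id")

  purrr::map_dfr(seq_len(frame$n_sectors), function(k) {
    sm <- sector_mask(frame, k, grid) * (roi > 0)
    vs <- velocity_stats(maps$velocity_magnitude, roi = sm)
    msk_k <- mask * sm
    dia <- if (!is.null(dt2) && any(skel > 0 & sm > 0))
      mean(dt2[skel > 0 & sm > 0]) else NA_real_
    fd <- if (sum(msk_k) > 0)
      tryCatch(suppressWarnings(fractal_number(msk_k)$fractal_number),
               error = function(e) NA_real_) else NA_real_
    tk <- tort$tortuosity[tort$sector == k]
    tibble(sector = k, roi_px = sum(sm > 0),
           mean_velocity = vs$mean_velocity,
           sd_velocity = vs$sd_velocity,
           mean_tortuosity = if (length(tk)) mean(tk) else NA_real_,
           n_tracks = length(tk),
           mean_diameter = dia,
           vessel_density = if (sum(sm > 0)) vessel_density(msk_k, sm)
                            else NA_real_,
           fractal_number = fd)
  })
}

#' Quantify one testis: the five vascular parameters plus histograms
#'
#' Runs the full quantification chain on a set of SR maps and the tracks they
#' were built from: vessel binarization at the half-peak threshold,
#' skeletonization, diameter extraction, tortuosity, box-counting fractal
#' number, vessel density, non-zero velocity statistics, the three value
#' histograms, and (when a hilum is given) the 12-sector regional breakdown.
#'
#' @param maps an [sr_map_set()].
#' @param tracks the `mb_tracks` used to build the maps.
#' @param roi optional binary ROI raster on the SR grid.
#' @param hilum_mm,axis optional sector frame parameters (see
#'   [sector_frame()]); sectors are skipped when `hilum_mm` is `NULL`.
#' @return object of class `quant_result`: the five scalars, per-value
#'   vectors, the three histograms and the sector tibble.
#' @seealso [tidy.quant_result()]
#' @export
quantify_testis <- function(maps, tracks, roi = NULL, hilum_mm = NULL,
                            axis = c(1, 0)) {
  stopifnot(inherits(maps, "sr_map_set"))
  grid <- maps$grid
  mask <- binarize_vessels(maps$density, maps$blur_sd, roi = roi)
  skel <- centerlines(mask)
  dia <- vessel_diameters(skel, mask, grid)
  tort <- track_tortuosity(tracks)
  vs <- velocity_stats(maps$velocity_magnitude, roi = roi)
  fd <- tryCatch(fractal_number(mask), error = function(e) NULL)
  vmag <- maps$velocity_magnitude
  vnz <- if (is.null(roi)) vmag[vmag > 0] else vmag[vmag > 0 & roi > 0]

  hist_of <- function(values, what) {
    if (!length(values))
      return(tibble(bin_lo = numeric(), bin_hi = numeric(),
                    fraction = numeric()))
    cohort_histograms(list(values), default_bins(what))$distribution
  }
  sectors <- NULL
  if (!is.null(hilum_mm))
    sectors <- sector_metrics(maps, tracks,
                              sector_frame(hilum_mm, axis), roi = roi)
  structure(list(
    mean_velocity = vs$mean_velocity, sd_velocity = vs$sd_velocity,
    mean_tortuosity = tort$mean_tortuosity,
    mean_diameter = dia$mean_diameter_um,
    fractal_number = if (is.null(fd)) NA_real_ else fd$fractal_number,
    vessel_density = vessel_density(mask, roi),
    values = list(velocity = vnz, tortuosity = tort$per_track$tortuosity,
                  diameter = dia$diameters_um),
    histograms = list(velocity = hist_of(vnz, "velocity"),
                      tortuosity = hist_of(tort$per_track$tortuosity,
                                           "tortuosity"),
                      diameter = hist_of(dia$diameters_um, "diameter")),
    sectors = sectors,
    mask = mask, skeleton = skel), class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat("<quant_result>\n")
  cat(sprintf("  mean velocity   %.3f (SD %.3f) mm/s\n",
              x$mean_velocity, x$sd_velocity))
  cat(sprintf("  mean tortuosity %.3f\n", x$mean_tortuosity))
  cat(sprintf("  mean diameter   %.1f um\n", x$mean_diameter))
  cat(sprintf("  fractal number  %.3f\n", x$fractal_number))
  cat(sprintf("  vessel density  %.3f\n", x$vessel_density))
  if (!is.null(x$sectors)) cat("  + 12-sector regional metrics\n")
  invisible(x)
}

#' Tidy a quantification result into a one-row tibble
#' @param x a `quant_result`.
#' @param ... unused.
#' @return tibble with the five vascular parameters (and `sd_velocity`).
#' @method tidy quant_result
#' @export
tidy.quant_result <- function(x, ...) {
  tibble(mean_velocity = x$mean_velocity, sd_velocity = x$sd_velocity,
         mean_tortuosity = x$mean_tortuosity,
         mean_diameter = x$mean_diameter,
         fractal_number = x$fractal_number,
         vessel_density = x$vessel_density)
}
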