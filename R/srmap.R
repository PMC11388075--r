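#' Super-resolution grid
#'
#' The SR raster geometry: the acquisition grid refined by an integer
#' upsampling factor. Row 0/col 0 is the image top-left; rows increase with
#' depth. The default factor of 4 puts SR pixels at a quarter of the
#' acquisition pitch, the scale at which neighboring microvessels separate.
#'
#' @param n_row,n_col acquisition-grid dimensions (px).
#' @param pixel_spacing_mm acquisition pixel pitch, mm/px.
#' @param upsampling_factor integer >= 1.
#' @return list of class `sr_grid` with `dim` (SR rows, cols),
#'   `sr_spacing_mm`, `upsampling_factor`, `pixel_spacing_mm`.
#' @export
sr_grid <- function(n_row, n_col, pixel_spacing_mm, upsampling_factor = 4L) {
  upsampling_factor <- as.integer(upsampling_factor)
  stopifnot(upsampling_factor >= 1L, pixel_spacing_mm > 0)
  structure(list(
    dim = c(n_row * upsampling_factor, n_col * upsampling_factor),
    sr_spacing_mm = pixel_spacing_mm / upsampling_factor,
    upsampling_factor = upsampling_factor,
    pixel_spacing_mm = pixel_spacing_mm), class = "sr_grid")
}

#' @export
print.sr_grid <- function(x, ...) {
  cat(sprintf("<sr_grid> %d x %d SR px, %.4g mm/px (x%d)\n",
              x$dim[1], x$dim[2], x$sr_spacing_mm, x$upsampling_factor))
  invisible(x)
}

# mm position -> SR pixel index (1-based, sub-pixel)
sr_px <- function(mm, grid) mm / grid$sr_spacing_mm + 1

# pixels traversed by each velocity segment of each track on the SR grid:
# tibble (row, col, vx, vy, seg)
track_segments_px <- function(tracks, grid) {
  tr <- as_tibble(tracks)
  tr <- tr[order(tr$track_id, tr$frame), ]
  n <- nrow(tr)
  empty <- tibble(row = integer(), col = integer(), vx = numeric(),
                  vy = numeric(), seg = integer(), tid = integer())
  if (n < 2L) return(empty)
  # segment = consecutive rows of the same track
  first <- seq_len(n - 1L)
  keep <- tr$track_id[first] == tr$track_id[first + 1L]
  first <- first[keep]
  if (!length(first)) return(empty)
  out <- vector("list", length(first))
  for (k in seq_along(first)) {
    i <- first[k]
    px <- bresenham(sr_px(tr$y_mm[i], grid), sr_px(tr$x_mm[i], grid),
                    sr_px(tr$y_mm[i + 1L], grid),
                    sr_px(tr$x_mm[i + 1L], grid))
    px <- clip_pixels(px, grid$dim[1], grid$dim[2])
    if (!nrow(px)) next
    out[[k]] <- cbind(px, vx = rep(tr$vx_mm_s[i], nrow(px)),
                      vy = rep(tr$vy_mm_s[i], nrow(px)),
                      seg = rep(k, nrow(px)),
                      tid = rep(tr$track_id[i], nrow(px)))
  }
  m <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(m) || !nrow(m)) return(empty)
  tibble(row = as.integer(m[, 1]), col = as.integer(m[, 2]),
         vx = m[, 3], vy = m[, 4], seg = as.integer(m[, 5]),
         tid = as.integer(m[, 6]))
}

#' Accumulate track trajectories into a super-resolution density map
#'
#' Each consecutive pair of localizations is rasterized as a line on the SR
#' grid (each traversed pixel incremented once per traversal); the count
#' raster is then blurred with an isotropic Gaussian whose SD equals the
#' localization uncertainty expressed in SR pixels.
#'
#' @param tracks an `mb_tracks` tibble.
#' @param grid an [sr_grid()].
#' @param localization_uncertainty_sr_px blur SD in SR pixels. The default
#'   of 1 SR pixel (a quarter acquisition pixel at the default upsampling of
#'   4) matches the sub-pixel precision the intensity-weighted centroid
#'   detector achieves on well-separated blobs.
#' @return density raster (matrix) with attributes `sr_grid` and `blur_sd`.
#' @export
accumulate_density <- function(tracks, grid,
                               localization_uncertainty_sr_px = 1) {
  segs <- track_segments_px(tracks, grid)
  dens <- matrix(0, grid$dim[1], grid$dim[2])
  if (nrow(segs)) {
    # consecutive segments of one track share their junction pixel; count a
    # pixel once per traversal of the track, not once per segment endpoint
    dup <- c(FALSE, segs$tid[-1] == segs$tid[-nrow(segs)] &
                    segs$row[-1] == segs$row[-nrow(segs)] &
                    segs$col[-1] == segs$col[-nrow(segs)])
    counts <- dplyr::count(segs[!dup, ], .data$row, .data$col)
    dens[cbind(counts$row, counts$col)] <- counts$n
  }
  out <- gauss_blur(dens, localization_uncertainty_sr_px)
  attr(out, "sr_grid") <- grid
  attr(out, "blur_sd") <- localization_uncertainty_sr_px
  out
}

#' Super-resolution velocity magnitude and direction maps
#'
#' The flow velocity of each SR pixel is the vector mean of the velocity
#' vectors of all track segments rasterized through it; the magnitude map is
#' the norm of that mean. The direction map encodes the axial flow sense as a
#' signed magnitude: positive toward the transducer (up the image), negative
#' away — the red/blue convention of directional ULM rendering. The full flow
#' angle is retained as attribute `angle`.
#'
#' @inheritParams accumulate_density
#' @return list with `magnitude` and `direction` rasters (attributes
#'   `sr_grid`; `angle` on the magnitude raster).
#' @export
velocity_maps <- function(tracks, grid) {
  segs <- track_segments_px(tracks, grid)
  mag <- matrix(0, grid$dim[1], grid$dim[2])
  dir <- matrix(0, grid$dim[1], grid$dim[2])
  ang <- matrix(NA_real_, grid$dim[1], grid$dim[2])
  if (nrow(segs)) {
    agg <- dplyr::summarise(
      dplyr::group_by(segs, .data$row, .data$col),
      vx = mean(.data$vx), vy = mean(.data$vy), .groups = "drop")
    m <- sqrt(agg$vx^2 + agg$vy^2)
    idx <- cbind(agg$row, agg$col)
    mag[idx] <- m
    # y/rows grow away from the transducer: vy < 0 is flow toward it
    dir[idx] <- ifelse(agg$vy <= 0, m, -m)
    ang[idx] <- atan2(-agg$vy, agg$vx)
  }
  attr(mag, "sr_grid") <- grid
  attr(mag, "angle") <- ang
  attr(dir, "sr_grid") <- grid
  list(magnitude = mag, direction = dir)
}

#' Maximum intensity projection of the bubble signal
#'
#' Per-pixel temporal maximum of the background-subtracted CEUS sequence.
#' The background is the per-pixel temporal median by default; negative
#' residuals are clamped at zero before the maximum.
#'
#' @param ceus a `frame_sequence`.
#' @param background `"median"` (temporal median, default) or `"none"`.
#' @return matrix with attribute `spacing_mm`.
#' @export
mip <- function(ceus, background = c("median", "none")) {
  stopifnot(inherits(ceus, "frame_sequence"))
  background <- match.arg(background)
  fr <- ceus$frames
  if (background == "median")
    fr <- sweep(fr, c(1, 2), apply(fr, c(1, 2), median), "-")
  out <- apply(pmax(fr, 0), c(1, 2), max)
  attr(out, "spacing_mm") <- ceus$pixel_spacing_mm
  out
}

#' Normalized Bernoulli pressure map with isobars
#'
#' Under the simplified Bernoulli relation the dynamic pressure is
#' proportional to the square of the flow speed; after max-normalization the
#' proportionality constant cancels, giving `pressure = v^2 / max(v^2)` in
#' `[0, 1]`. Isobar contour levels are `n_isobars` equally spaced values in
#' (0, 1) and their contour polylines are computed on the pressure raster.
#'
#' @param velocity_magnitude non-negative raster from [velocity_maps()].
#' @param n_isobars number of isobar levels (default 9, i.e. 0.1 ... 0.9).
#' @return list of class `pressure_map`: `pressure` raster in `[0, 1]`,
#'   `levels`, and `isobars` (tibble `level`, `contour`, `x`, `y` in SR px).
#' @export
pressure_map <- function(velocity_magnitude, n_isobars = 9L) {
  v <- velocity_magnitude
  if (any(v < 0)) abort("velocity magnitude must be non-negative")
  vmax2 <- max(v)^2
  if (vmax2 == 0) abort("no flow signal: velocity raster is all zero")
  p <- v^2 / vmax2
  levels <- seq_len(n_isobars) / (n_isobars + 1)
  cl <- if (nrow(p) >= 2L && ncol(p) >= 2L)
    grDevices::contourLines(x = seq_len(nrow(p)), y = seq_len(ncol(p)),
                            z = p, levels = levels)
  else list()
  isobars <- purrr::map_dfr(seq_along(cl), function(i)
    tibble(level = cl[[i]]$level, contour = i,
           x = cl[[i]]$y, y = cl[[i]]$x))
  attr(p, "sr_grid") <- attr(velocity_magnitude, "sr_grid")
  structure(list(pressure = p, levels = levels, isobars = isobars),
            class = "pressure_map")
}

#' Centered log-magnitude Fourier spectrum of an SR image
#'
#' 2-D discrete Fourier transform magnitude, zero frequency shifted to the
#' raster center, log-scaled as `log1p(|F|)`. The unshifted DC magnitude
#' (equal to the plain sum of image values) is kept as attribute `dc`.
#'
#' @param sr_image numeric matrix.
#' @return log-magnitude spectrum matrix with attributes `dc` and
#'   `magnitude` (the unlogged, centered magnitude).
#' @export
fourier_spectrum <- function(sr_image) {
  F <- fft(sr_image)
  mag <- Mod(F)
  mag <- fftshift2(mag)
  out <- log1p(mag)
  attr(out, "magnitude") <- mag
  attr(out, "dc") <- Mod(F[1, 1])
  out
}

fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c((floor(nr / 2) + 1):nr, 1:floor(nr / 2))
  ci <- c((floor(nc / 2) + 1):nc, 1:floor(nc / 2))
  m[ri, ci]
}

#' Build the full set of co-registered SR maps from tracks
#'
#' Convenience wrapper producing the density, velocity-magnitude, direction
#' and normalized pressure rasters on one grid.
#'
#' @inheritParams accumulate_density
#' @param n_isobars passed to [pressure_map()]; pressure is skipped (with a
#'   message) when there is no flow signal.
#' @return list of class `sr_map_set`: `density`, `velocity_magnitude`,
#'   `direction`, `pressure` (or `NULL`), `grid`, `blur_sd`.
#' @export
sr_map_set <- function(tracks, grid, localization_uncertainty_sr_px = 1,
                       n_isobars = 9L) {
  dens <- accumulate_density(tracks, grid, localization_uncertainty_sr_px)
  vel <- velocity_maps(tracks, grid)
  pres <- if (max(vel$magnitude) > 0)
    pressure_map(vel$magnitude, n_isobars) else NULL
  structure(list(density = dens, velocity_magnitude = vel$magnitude,
                 direction = vel$direction, pressure = pres, grid = grid,
                 blur_sd = localization_uncertainty_sr_px),
            class = "sr_map_set")
}

#' @export
print.sr_map_set <- function(x, ...) {
  cat(sprintf("<sr_map_set> %d x %d SR px, peak density %.3g, max speed %.3g mm/s\n",
              x$grid$dim[1], x$grid$dim[2], max(x$density),
              max(x$velocity_magnitude)))
  invisible(x)
}
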