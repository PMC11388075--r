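#' Acquisition configuration for the microbubble simulator
#'
#' Bundles the imaging parameters of a contrast-enhanced acquisition. Defaults
#' follow the clinical protocol the pipeline targets: side-by-side B-mode and
#' CEUS at 114 Hz; a 30 s acquisition (shorten `duration_s` for quick runs).
#'
#' @param frame_rate_hz frames per second (> 0).
#' @param duration_s acquisition length in seconds (> 0).
#' @param pixel_spacing_mm pixel pitch, mm per pixel.
#' @param psf_sigma_mm standard deviation of the isotropic Gaussian
#'   point-spread function used to render each microbubble (> 0).
#' @param mb_rate_hz Poisson arrival rate of microbubbles per vessel segment
#'   inlet, bubbles per second.
#' @param speckle_snr_db blob peak amplitude over mean speckle amplitude, dB.
#' @param motion_amplitude_px amplitude of the global sinusoidal tissue motion
#'   (lateral; axial amplitude is half, opposite phase), px.
#' @param motion_period_s period of the tissue motion, s (breathing-like).
#' @param bmode_bubble_amp microbubble amplitude on the B-mode channel
#'   (relative to blob peak 1 on CEUS); the clutter the SVD step suppresses.
#' @param lateral_dispersion_mm per-frame SD of the lateral random walk each
#'   bubble performs inside the lumen (reflected at the walls). Models the
#'   shear-induced dispersion that spreads real bubbles across streamlines;
#'   default 0.003 mm/frame.
#' @param seed integer RNG seed; the whole simulation is reproducible given it.
#' @return list of class `acquisition_config`.
#' @export
acquisition_config <- function(frame_rate_hz = 114,
                               duration_s = 30,
                               pixel_spacing_mm = 0.1,
                               psf_sigma_mm = 0.25,
                               mb_rate_hz = 2,
                               speckle_snr_db = 20,
                               motion_amplitude_px = 1,
                               motion_period_s = 3.5,
                               bmode_bubble_amp = 0.5,
                               lateral_dispersion_mm = 0.003,
                               seed = 1L) {
  stopifnot(frame_rate_hz > 0, duration_s > 0, pixel_spacing_mm > 0,
            psf_sigma_mm > 0, mb_rate_hz >= 0, motion_period_s > 0,
            motion_amplitude_px >= 0)
  structure(list(
    frame_rate_hz = frame_rate_hz, duration_s = duration_s,
    pixel_spacing_mm = pixel_spacing_mm, psf_sigma_mm = psf_sigma_mm,
    mb_rate_hz = mb_rate_hz, speckle_snr_db = speckle_snr_db,
    motion_amplitude_px = motion_amplitude_px,
    motion_period_s = motion_period_s,
    bmode_bubble_amp = bmode_bubble_amp,
    lateral_dispersion_mm = lateral_dispersion_mm,
    seed = as.integer(seed)), class = "acquisition_config")
}

#' Simulate microbubble transit through a vascular phantom
#'
#' Generates paired CEUS and B-mode frame sequences with full ground truth.
#' Bubbles are seeded at each segment inlet as a Poisson process and advected
#' along the centerline at the segment's plug-flow speed; each bubble is
#' rendered per frame as an isotropic Gaussian blob of SD `psf_sigma_mm` on a
#' Rayleigh speckle background. A smooth global sinusoidal translation
#' (breathing-like tissue motion) is applied identically to both channels;
#' the truth table records every bubble's motion-displaced position.
#'
#' @param phantom a `vascular_phantom` from [build_phantom()].
#' @param cfg an `acquisition_config`.
#' @return list with elements
#'   \describe{
#'     \item{ceus, bmode}{`frame_sequence` objects.}
#'     \item{truth}{list: `positions` tibble (`bubble_id`, `frame`, `x_mm`,
#'       `y_mm`, `vx_mm_s`, `vy_mm_s`, `crowded`), `motion` tibble (`frame`,
#'       `dx_px`, `dy_px`), `n_bubbles`, and the phantom truth.}
#'   }
#' @examples
#' ph <- build_phantom("straight", list(length_mm = 6, radius_mm = 0.15),
#'                     fov_mm = c(8, 4))
#' cfg <- acquisition_config(duration_s = 0.5, motion_amplitude_px = 0, seed = 7)
#' sim <- simulate_mb_transit(ph, cfg)
#' @export
simulate_mb_transit <- function(phantom, cfg) {
  stopifnot(inherits(phantom, "vascular_phantom"),
            inherits(cfg, "acquisition_config"))
  if (nrow(phantom$segments) == 0L) abort("phantom has no segments")

  sp <- cfg$pixel_spacing_mm
  nr <- ceiling(phantom$fov_mm[2] / sp)
  nc <- ceiling(phantom$fov_mm[1] / sp)
  nfr <- max(1L, round(cfg$frame_rate_hz * cfg$duration_s))
  tf <- (seq_len(nfr) - 1L) / cfg$frame_rate_hz

  # global sinusoidal tissue motion, px (lateral dx, axial dy)
  dx <- cfg$motion_amplitude_px * sin(2 * pi * tf / cfg$motion_period_s)
  dy <- -0.5 * cfg$motion_amplitude_px * sin(2 * pi * tf / cfg$motion_period_s)
  motion <- tibble(frame = seq_len(nfr), dx_px = dx, dy_px = dy)

  with_seed(cfg$seed, {
    pos <- sample_bubble_positions(phantom, cfg, nfr)

    # speckle backgrounds: smoothed Rayleigh fields, mean set by SNR
    mean_amp <- 10^(-cfg$speckle_snr_db / 20)
    mk_speckle <- function(target_mean) {
      f <- matrix(sqrt(-2 * log(runif(nr * nc))), nr, nc)  # Rayleigh(1)
      f <- gauss_blur(f, 1.2)
      f * target_mean / mean(f)
    }
    ceus_bg <- mk_speckle(mean_amp)
    bmode_bg <- mk_speckle(1)

    psf_px <- cfg$psf_sigma_mm / sp
    ceus <- array(0, c(nr, nc, nfr))
    bmode <- array(0, c(nr, nc, nfr))
    for (f in seq_len(nfr)) {
      cf <- shift_image(ceus_bg, dx[f], dy[f])
      bf <- shift_image(bmode_bg, dx[f], dy[f])
      pf <- pos[pos$frame == f, , drop = FALSE]
      if (nrow(pf)) {
        for (i in seq_len(nrow(pf))) {
          cpx <- mm_to_px(pf$x_mm[i], sp) + dx[f]
          rpx <- mm_to_px(pf$y_mm[i], sp) + dy[f]
          cf <- add_blob(cf, rpx, cpx, 1, psf_px)
          if (cfg$bmode_bubble_amp > 0)
            bf <- add_blob(bf, rpx, cpx, cfg$bmode_bubble_amp, psf_px)
        }
      }
      ceus[, , f] <- cf
      bmode[, , f] <- bf
    }

    # truth positions include the injected motion (what the images show)
    pos$x_mm <- pos$x_mm + dx[pos$frame] * sp
    pos$y_mm <- pos$y_mm + dy[pos$frame] * sp
    pos <- flag_crowded(pos, 2 * cfg$psf_sigma_mm)

    list(
      ceus = frame_sequence(ceus, sp, cfg$frame_rate_hz, "ceus"),
      bmode = frame_sequence(bmode, sp, cfg$frame_rate_hz, "bmode"),
      truth = list(
        positions = pos,
        motion = motion,
        n_bubbles = length(unique(pos$bubble_id)),
        phantom = phantom$truth))
  })
}

# Poisson seeding at segment inlets, plug-flow advection along the centerline
sample_bubble_positions <- function(phantom, cfg, nfr) {
  tf <- (seq_len(nfr) - 1L) / cfg$frame_rate_hz
  out <- list()
  bid <- 0L
  for (s in seq_len(nrow(phantom$segments))) {
    seg <- phantom$segments[s, ]
    cl <- seg$centerline[[1]]
    arc <- c(0, cumsum(sqrt(rowSums(diff(cl)^2))))
    total <- arc[length(arc)]
    v <- seg$peak_velocity_mm_s
    if (v <= 0) next
    horizon <- cfg$duration_s + total / v
    n <- rpois(1L, cfg$mb_rate_hz * horizon)
    if (n == 0L) next
    births <- sort(runif(n, -total / v, cfg$duration_s))
    # unit tangent per polyline vertex for velocity vectors
    tang <- rbind(diff(cl), diff(cl)[nrow(cl) - 1L, , drop = FALSE])
    tang <- tang / sqrt(rowSums(tang^2))
    # bubbles travel anywhere in the lumen: lateral offset from the
    # centerline starts uniform in (-radius, radius) and performs a small
    # reflected random walk (shear-induced dispersion); plug flow = same
    # axial speed at every offset
    offs <- runif(n, -seg$radius_mm, seg$radius_mm)
    disp <- cfg$lateral_dispersion_mm %||% 0
    for (b in seq_len(n)) {
      bid <- bid + 1L
      d <- v * (tf - births[b])
      live <- which(d >= 0 & d <= total)
      if (!length(live)) next
      xi <- stats::approx(arc, cl[, 1], xout = d[live])$y
      yi <- stats::approx(arc, cl[, 2], xout = d[live])$y
      ti <- findInterval(d[live], arc, all.inside = TRUE)
      nx <- -tang[ti, 2]; ny <- tang[ti, 1]  # unit normal
      ob <- offs[b]
      if (disp > 0 && length(live) > 1L) {
        ob <- ob + c(0, cumsum(rnorm(length(live) - 1L, sd = disp)))
        ob <- reflect_interval(ob, -seg$radius_mm, seg$radius_mm)
      }
      out[[length(out) + 1L]] <- tibble(
        bubble_id = bid, frame = live,
        x_mm = xi + ob * nx, y_mm = yi + ob * ny,
        vx_mm_s = seg$flow_sign * v * tang[ti, 1],
        vy_mm_s = seg$flow_sign * v * tang[ti, 2])
    }
  }
  if (!length(out))
    return(tibble(bubble_id = integer(), frame = integer(),
                  x_mm = numeric(), y_mm = numeric(),
                  vx_mm_s = numeric(), vy_mm_s = numeric()))
  dplyr::bind_rows(out)
}

# fold values into [lo, hi] by reflection at the boundaries
reflect_interval <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

add_blob <- function(img, r0, c0, amp, sigma_px) {
  nr <- nrow(img); nc <- ncol(img)
  r <- ceiling(4 * sigma_px)
  rs <- max(1L, floor(r0 - r)):min(nr, ceiling(r0 + r))
  cs <- max(1L, floor(c0 - r)):min(nc, ceiling(c0 + r))
  if (!length(rs) || !length(cs)) return(img)
  g <- amp * outer(exp(-(rs - r0)^2 / (2 * sigma_px^2)),
                   exp(-(cs - c0)^2 / (2 * sigma_px^2)))
  img[rs, cs] <- img[rs, cs] + g
  img
}

flag_crowded <- function(pos, min_sep_mm) {
  pos$crowded <- FALSE
  for (f in unique(pos$frame)) {
    idx <- which(pos$frame == f)
    if (length(idx) < 2L) next
    dmat <- as.matrix(stats::dist(pos[idx, c("x_mm", "y_mm")]))
    diag(dmat) <- Inf
    pos$crowded[idx] <- apply(dmat, 1, min) < min_sep_mm
  }
  pos
}
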