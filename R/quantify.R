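#' Binarize the SR density map into a vessel mask
#'
#' The threshold is half the peak value that a single unit-mass line
#' traversal attains after the Gaussian blur used in density accumulation
#' (i.e. half the blurred single-line amplitude, computed from the same
#' discrete kernel). Referencing one traversal — not the global density peak —
#' keeps faint single-pass vessels detectable next to multi-pass trunks.
#'
#' After thresholding, the mask is morphologically closed with a small disc
#' (default 5 SR px): trajectory sampling is finite, so a vessel interior can
#' contain sub-FWHM gaps between neighboring trajectories that thresholding
#' leaves open; closing bridges them without dilating smooth vessel
#' boundaries. Set `close_px = 0` for the bare threshold mask.
#'
#' @param density raster from [accumulate_density()].
#' @param blur_sd_sr_px blur SD used for the density map; default taken from
#'   the raster's `blur_sd` attribute.
#' @param roi optional binary ROI raster (same shape); default all-inside.
#' @param close_px diameter (SR px) of the disc used to morphologically
#'   close the thresholded mask; `0` disables.
#' @return binary matrix (vessel mask) with attributes `sr_grid`, `roi`,
#'   `threshold`.
#' @export
binarize_vessels <- function(density, blur_sd_sr_px = NULL, roi = NULL,
                             close_px = 5L) {
  blur_sd_sr_px <- blur_sd_sr_px %||% attr(density, "blur_sd")
  if (is.null(blur_sd_sr_px))
    abort("blur_sd_sr_px unknown: pass it or use accumulate_density() output")
  thr <- 0.5 * blurred_line_peak(blur_sd_sr_px)
  mask <- (density >= thr) * 1L
  if (close_px >= 2L && any(mask > 0))
    mask <- matrix(as.integer(EBImage::closing(
      mask > 0, EBImage::makeBrush(as.integer(close_px), "disc"))),
      nrow(mask))
  if (!is.null(roi)) {
    stopifnot(all(dim(roi) == dim(density)))
    mask <- mask * (roi > 0)
  }
  mask <- matrix(as.integer(mask), nrow(density))
  attr(mask, "sr_grid") <- attr(density, "sr_grid")
  attr(mask, "roi") <- roi
  attr(mask, "threshold") <- thr
  mask
}

#' Morphological centerlines (skeleton) of a vessel mask
#'
#' One-pixel-wide, topology-preserving thinning (Zhang-Suen) of the binary
#' vessel mask, followed by spur pruning: endpoint pixels are removed
#' iteratively for as many steps as the mask's largest half-width, which
#' deletes the short side branches that thinning grows from ragged vessel
#' boundaries while barely shortening true centerlines. A connected
#' component whose skeleton is consumed entirely keeps its deepest
#' (maximum-distance) pixel. The skeleton is always a subset of the mask and
#' keeps its connected components.
#'
#' @param mask binary matrix from [binarize_vessels()].
#' @param prune spur-pruning iterations: `"auto"` (default, the mask's
#'   maximum half-width in pixels), an integer, or `0` to disable.
#' @return binary skeleton matrix (same attributes).
#' @export
centerlines <- function(mask, prune = "auto") {
  m <- mask > 0
  sk <- zhang_suen(m)
  if (!identical(prune, 0) && any(sk)) {
    dt <- EBImage::distmap(m, metric = "euclidean")@.Data
    n_iter <- if (identical(prune, "auto")) ceiling(max(dt)) + 1L
              else as.integer(prune)
    if (n_iter > 0L) {
      lab0 <- EBImage::bwlabel(sk)@.Data
      pruned <- prune_spurs(sk, n_iter)
      # restore one representative pixel for any fully consumed component
      for (comp in setdiff(unique(lab0[lab0 > 0]),
                           unique(lab0[pruned & lab0 > 0]))) {
        idx <- which(lab0 == comp)
        pruned[idx[which.max(dt[idx])]] <- TRUE
      }
      sk <- pruned
    }
  }
  out <- matrix(as.integer(sk), nrow(mask))
  attr(out, "sr_grid") <- attr(mask, "sr_grid")
  out
}

# iteratively delete skeleton endpoints (<= 1 eight-neighbor)
prune_spurs <- function(sk, n_iter) {
  nr <- nrow(sk); nc <- ncol(sk)
  for (i in seq_len(n_iter)) {
    pad <- matrix(FALSE, nr + 2L, nc + 2L)
    pad[2:(nr + 1L), 2:(nc + 1L)] <- sk
    nb <- pad[1:nr, 2:(nc + 1L)] + pad[3:(nr + 2L), 2:(nc + 1L)] +
      pad[2:(nr + 1L), 1:nc] + pad[2:(nr + 1L), 3:(nc + 2L)] +
      pad[1:nr, 1:nc] + pad[1:nr, 3:(nc + 2L)] +
      pad[3:(nr + 2L), 1:nc] + pad[3:(nr + 2L), 3:(nc + 2L)]
    ends <- sk & nb <= 1L
    if (!any(ends)) break
    sk <- sk & !ends
  }
  sk
}

# Zhang-Suen thinning on a logical matrix, vectorized over the whole image
zhang_suen <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- img
  nb <- function(m, dr, dc) m[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p2 <- nb(pad, -1L, 0L); p3 <- nb(pad, -1L, 1L); p4 <- nb(pad, 0L, 1L)
      p5 <- nb(pad, 1L, 1L); p6 <- nb(pad, 1L, 0L); p7 <- nb(pad, 1L, -1L)
      p8 <- nb(pad, 0L, -1L); p9 <- nb(pad, -1L, -1L)
      cur <- pad[2:(nr + 1L), 2:(nc + 1L)]
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (phase == 1L) {
        cond <- cur & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- cur & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        changed <- TRUE
        cur[cond] <- FALSE
        pad[2:(nr + 1L), 2:(nc + 1L)] <- cur
      }
    }
    if (!changed) break
  }
  pad[2:(nr + 1L), 2:(nc + 1L)]
}

#' Vessel diameters from skeleton and mask
#'
#' The diameter at each centerline pixel is twice the Euclidean distance from
#' that pixel to the nearest background pixel (distance transform of the
#' mask), converted to micrometers via the SR pixel pitch.
#'
#' @param skeleton binary skeleton from [centerlines()].
#' @param mask binary vessel mask containing the skeleton.
#' @param grid an [sr_grid()]; default from the mask attribute.
#' @return list: `diameters_um` (per skeleton pixel), `mean_diameter_um`
#'   (`NA` for an empty skeleton), `n_points`.
#' @export
vessel_diameters <- function(skeleton, mask, grid = NULL) {
  grid <- grid %||% attr(mask, "sr_grid")
  if (is.null(grid)) abort("grid unknown: pass an sr_grid")
  stopifnot(all(dim(skeleton) == dim(mask)))
  if (any(skeleton > 0 & !(mask > 0)))
    abort("skeleton must be a subset of the mask")
  if (!any(skeleton > 0))
    return(list(diameters_um = numeric(), mean_diameter_um = NA_real_,
                n_points = 0L))
  dt <- EBImage::distmap(mask > 0, metric = "euclidean")
  d_px <- 2 * dt@.Data[skeleton > 0]
  d_um <- d_px * grid$sr_spacing_mm * 1000
  list(diameters_um = d_um, mean_diameter_um = mean(d_um),
       n_points = length(d_um))
}

#' Track tortuosity
#'
#' Tortuosity of a microbubble track is its total path length divided by the
#' straight-line distance between its endpoints (>= 1; 1 for a straight
#' vessel). Tracks with coincident endpoints (zero chord) are excluded and
#' tallied.
#'
#' @param tracks an `mb_tracks` tibble (>= 2 localizations per track).
#' @return list: `per_track` tibble (`track_id`, `path_length_mm`,
#'   `chord_length_mm`, `tortuosity`), `mean_tortuosity`,
#'   `n_excluded_zero_chord`.
#' @export
track_tortuosity <- function(tracks) {
  ts <- track_summary(tracks)
  ok <- ts$chord_length_mm > 0
  per <- tibble(track_id = ts$track_id[ok],
                path_length_mm = ts$path_length_mm[ok],
                chord_length_mm = ts$chord_length_mm[ok],
                tortuosity = ts$path_length_mm[ok] / ts$chord_length_mm[ok])
  list(per_track = per,
       mean_tortuosity = if (nrow(per)) mean(per$tortuosity) else NA_real_,
       n_excluded_zero_chord = sum(!ok))
}

#' Box-counting fractal number of a vessel mask
#'
#' The mask is covered by square boxes of decreasing size `s`; `N(s)` counts
#' boxes containing at least one vessel pixel. Local slopes between adjacent
#' scales, `delta log N / delta log(1/s)`, are averaged over the
#' automatically selected stable range: the longest run of at least three
#' consecutive slopes whose pairwise spread is at most `stable_tol` (ties
#' broken toward the smaller spread; if no run qualifies, all slopes are
#' averaged with a warning).
#'
#' @param mask binary matrix.
#' @param box_sizes strictly descending box edge lengths in pixels; default
#'   powers of 2 from half the smaller mask dimension down to 2.
#' @param stable_tol maximum pairwise slope spread within the stable range.
#' @return list: `scales` tibble (`box_size`, `n_boxes`, and per-interval
#'   `local_slope`), `fractal_number`, `stable_range` (indices of slopes
#'   used).
#' @export
fractal_number <- function(mask, box_sizes = NULL, stable_tol = 0.2) {
  m <- mask > 0
  if (!any(m)) abort("mask is empty")
  if (is.null(box_sizes)) {
    smax <- 2^floor(log2(min(dim(m)) / 2))
    box_sizes <- 2^(log2(smax):1)
  }
  box_sizes <- as.integer(box_sizes)
  if (is.unsorted(rev(box_sizes), strictly = TRUE))
    abort("box_sizes must be strictly descending")
  if (length(box_sizes) < 3L)
    abort("need at least 3 box sizes (scales) for a fractal estimate")
  N <- vapply(box_sizes, function(s) {
    ri <- (seq_len(nrow(m)) - 1L) %/% s
    ci <- (seq_len(ncol(m)) - 1L) %/% s
    # sum within s x s blocks, then count occupied boxes
    agg <- rowsum(t(rowsum(m * 1L, ri)), ci)
    sum(agg > 0)
  }, numeric(1))
  logN <- log(N)
  loginv <- log(1 / box_sizes)
  slopes <- diff(logN) / diff(loginv)
  run <- stable_run(slopes, stable_tol)
  if (is.null(run)) {
    warn("no stable slope range found; averaging all local slopes")
    run <- seq_along(slopes)
  }
  list(scales = tibble(box_size = box_sizes, n_boxes = N,
                       local_slope = c(NA, slopes)),
       fractal_number = mean(slopes[run]),
       stable_range = run)
}

# longest run of >=3 consecutive values with pairwise spread <= tol
stable_run <- function(x, tol) {
  n <- length(x)
  best <- NULL; best_len <- 0L; best_spread <- Inf
  for (i in seq_len(n)) for (j in i:n) {
    if (j - i + 1L < 3L) next
    sp <- max(x[i:j]) - min(x[i:j])
    if (sp <= tol) {
      len <- j - i + 1L
      if (len > best_len || (len == best_len && sp < best_spread)) {
        best <- i:j; best_len <- len; best_spread <- sp
      }
    }
  }
  best
}

#' Vessel density
#'
#' Area ratio of the binary vessel structure to the ROI.
#'
#' @param mask binary vessel mask.
#' @param roi binary ROI raster (same shape); default the mask's `roi`
#'   attribute, else the whole raster.
#' @return fraction in `[0, 1]`.
#' @export
vessel_density <- function(mask, roi = NULL) {
  roi <- roi %||% attr(mask, "roi")
  if (is.null(roi)) roi <- matrix(1L, nrow(mask), ncol(mask))
  stopifnot(all(dim(roi) == dim(mask)))
  if (!any(roi > 0)) abort("ROI is empty")
  sum(mask > 0 & roi > 0) / sum(roi > 0)
}

#' Mean and SD of flow velocity over the non-zero magnitude pixels
#'
#' @param magnitude velocity-magnitude raster (mm/s).
#' @param roi optional binary raster restricting the statistic.
#' @return list `mean_velocity`, `sd_velocity` (mm/s; `NA` with
#'   `n_nonzero = 0` when there is no flow signal), `n_nonzero`.
#' @export
velocity_stats <- function(magnitude, roi = NULL) {
  v <- magnitude
  if (!is.null(roi)) v <- v[roi > 0]
  v <- v[v > 0]
  if (!length(v))
    return(list(mean_velocity = NA_real_, sd_velocity = NA_real_,
                n_nonzero = 0L))
  list(mean_velocity = mean(v),
       sd_velocity = if (length(v) > 1L) sd(v) else 0,
       n_nonzero = length(v))
}

#' Cohort-averaged histograms
#'
#' Each patient's values are first normalized to a within-patient fraction
#' histogram (fractions summing to 1); the cohort distribution is the
#' unweighted mean of those fractions across patients, so every patient
#' contributes equally regardless of vessel count. Patients with no values
#' are skipped and tallied.
#'
#' @param per_patient_values list of numeric vectors, one per patient.
#' @param bin_edges increasing breaks; values outside are clamped into the
#'   end bins.
#' @return list: `distribution` tibble (`bin_lo`, `bin_hi`, `fraction`),
#'   `n_patients_used`, `n_patients_skipped`.
#' @export
cohort_histograms <- function(per_patient_values, bin_edges) {
  stopifnot(length(bin_edges) >= 2L, !is.unsorted(bin_edges))
  nb <- length(bin_edges) - 1L
  fr <- vapply(per_patient_values, function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(rep(NA_real_, nb))
    v <- pmin(pmax(v, bin_edges[1]), bin_edges[length(bin_edges)])
    h <- graphics::hist(v, breaks = bin_edges, plot = FALSE,
                        include.lowest = TRUE, right = FALSE)
    h$counts / length(v)
  }, numeric(nb))
  fr <- matrix(fr, nrow = nb)
  used <- !apply(fr, 2, anyNA)
  if (!any(used)) abort("all patients have empty value lists")
  avg <- rowMeans(fr[, used, drop = FALSE])
  list(distribution = tibble(bin_lo = bin_edges[-length(bin_edges)],
                             bin_hi = bin_edges[-1],
                             fraction = avg),
       n_patients_used = sum(used),
       n_patients_skipped = sum(!used))
}

#' Default histogram binning for the three distributions
#' @param what one of `"velocity"`, `"tortuosity"`, `"diameter"`.
#' @return numeric vector of bin edges (velocity: 0.5 mm/s bins on
#'   `[0, 10]`; tortuosity: 0.25 bins on `[1, 6]`; diameter: 20 um bins on
#'   `[0, 400]`).
#' @export
default_bins <- function(what = c("velocity", "tortuosity", "diameter")) {
  switch(match.arg(what),
         velocity = seq(0, 10, by = 0.5),
         tortuosity = seq(1, 6, by = 0.25),
         diameter = seq(0, 400, by = 20))
}
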