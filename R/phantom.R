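#' Build a vascular phantom with analytically known ground truth
#'
#' Constructs a 2-D vascular phantom — a set of vessel segments, each an
#' ordered centerline polyline (mm) with a radius, a plug-flow peak velocity
#' and a flow sign — inside a rectangular field of view. Phantoms carry their
#' own ground truth (per-segment arc length, chord length, tortuosity, and the
#' nominal vessel-area fraction), so downstream localization, mapping and
#' quantification stages can be scored against known values.
#'
#' Available geometries:
#' \describe{
#'   \item{`straight`}{one straight segment (`length_mm`, `angle_deg`).}
#'   \item{`sinusoid`}{`y = a sin(2*pi*x/lambda)` over `length_mm`; arc length
#'     computed by numeric quadrature and stored as ground truth.}
#'   \item{`bifurcating`}{symmetric binary tree of `depth` levels
#'     (`2^depth - 1` segments), branch length shrinking by `ratio`.}
#'   \item{`grid`}{parallel vertical lines at pitch `spacing_mm` (used for
#'     frequency-spectrum checks).}
#'   \item{`fractal_tree`}{a deeper self-similar binary tree (default depth 5)
#'     for space-filling masks.}
#' }
#'
#' @param kind one of `"straight"`, `"sinusoid"`, `"bifurcating"`, `"grid"`,
#'   `"fractal_tree"`.
#' @param params named list of geometry parameters (lengths, radii, angles,
#'   amplitudes ... in mm/degrees); see Details. Unknown geometry that exits
#'   the field of view is rejected.
#' @param fov_mm field of view `c(width, height)` in mm.
#' @param roi_spacing_mm pixel pitch of the stored binary ROI mask.
#' @param peak_velocity_mm_s plug-flow speed assigned to every segment unless
#'   overridden in `params`.
#' @return a `vascular_phantom`: list with `segments` (tibble with list-column
#'   `centerline`, columns `radius_mm`, `peak_velocity_mm_s`, `flow_sign`,
#'   `path_length_mm`, `chord_length_mm`, `tortuosity`), `fov_mm`, `roi_mask`,
#'   `roi_spacing_mm`, and `truth` (totals).
#' @examples
#' ph <- build_phantom("straight", list(length_mm = 8, radius_mm = 0.15))
#' ph$segments$tortuosity  # 1 for a straight vessel
#' @export
build_phantom <- function(kind = c("straight", "sinusoid", "bifurcating",
                                   "grid", "fractal_tree"),
                          params = list(),
                          fov_mm = c(10, 10),
                          roi_spacing_mm = 0.1,
                          peak_velocity_mm_s = 3) {
  kind <- match.arg(kind)
  p <- params
  v <- p$peak_velocity_mm_s %||% peak_velocity_mm_s
  radius <- p$radius_mm %||% 0.3
  w <- fov_mm[1]; h <- fov_mm[2]

  segs <- switch(kind,
    straight = {
      len <- p$length_mm %||% (0.8 * w)
      ang <- (p$angle_deg %||% 0) * pi / 180
      x0 <- p$x0_mm %||% ((w - len * abs(cos(ang))) / 2)
      y0 <- p$y0_mm %||% (h / 2)
      tt <- seq(0, len, length.out = p$n_points %||% 50L)
      list(cbind(x = x0 + tt * cos(ang), y = y0 + tt * sin(ang)))
    },
    sinusoid = {
      len <- p$length_mm %||% (0.8 * w)
      a <- p$amplitude_mm %||% 1
      lam <- p$wavelength_mm %||% (len / 2)
      x0 <- p$x0_mm %||% ((w - len) / 2)
      y0 <- p$y0_mm %||% (h / 2)
      xs <- seq(0, len, length.out = p$n_points %||% 400L)
      list(cbind(x = x0 + xs, y = y0 + a * sin(2 * pi * xs / lam)))
    },
    bifurcating = tree_centerlines(
      depth = p$depth %||% 3L,
      trunk_len = p$trunk_length_mm %||% (0.3 * h),
      ratio = p$ratio %||% 0.72,
      spread_deg = p$spread_deg %||% 35,
      root = c(p$x0_mm %||% (w / 2), p$y0_mm %||% (0.92 * h)),
      root_angle_deg = -90),
    grid = {
      s <- p$spacing_mm %||% 1
      margin <- p$margin_mm %||% (0.1 * w)
      xs <- seq(margin, w - margin, by = s)
      lapply(xs, function(x)
        cbind(x = c(x, x), y = c(0.1 * h, 0.9 * h)))
    },
    fractal_tree = tree_centerlines(
      depth = p$depth %||% 5L,
      trunk_len = p$trunk_length_mm %||% (0.28 * h),
      ratio = p$ratio %||% 0.7,
      spread_deg = p$spread_deg %||% 40,
      root = c(p$x0_mm %||% (w / 2), p$y0_mm %||% (0.95 * h)),
      root_angle_deg = -90)
  )

  radii <- rep_len(p$radii_mm %||% radius, length(segs))
  speeds <- rep_len(v, length(segs))
  phantom <- new_phantom(segs, radii, speeds, fov_mm, roi_spacing_mm)
  phantom$kind <- kind
  if (kind == "sinusoid") {
    a <- p$amplitude_mm %||% 1
    lam <- p$wavelength_mm %||% ((p$length_mm %||% (0.8 * w)) / 2)
    len <- p$length_mm %||% (0.8 * w)
    arc <- stats::integrate(function(x)
      sqrt(1 + (2 * pi * a / lam * cos(2 * pi * x / lam))^2),
      0, len, subdivisions = 1000L)$value
    phantom$truth$quadrature_arc_length_mm <- arc
  }
  phantom
}

new_phantom <- function(centerlines, radii, speeds, fov_mm, roi_spacing_mm) {
  stopifnot(length(centerlines) >= 1L)
  for (cl in centerlines) {
    if (nrow(cl) < 2L) abort("each centerline needs at least 2 points")
    if (any(cl[, 1] < 0 | cl[, 1] > fov_mm[1] |
            cl[, 2] < 0 | cl[, 2] > fov_mm[2]))
      abort(sprintf(
        "phantom geometry exits the field of view (%.3g x %.3g mm)",
        fov_mm[1], fov_mm[2]))
  }
  if (any(radii <= 0)) abort("segment radius must be > 0")
  if (any(speeds < 0)) abort("peak_velocity must be >= 0")
  path <- vapply(centerlines, polyline_length, numeric(1))
  chord <- vapply(centerlines, function(cl)
    sqrt(sum((cl[nrow(cl), ] - cl[1, ])^2)), numeric(1))
  segments <- tibble(
    segment = seq_along(centerlines),
    centerline = centerlines,
    radius_mm = radii,
    peak_velocity_mm_s = speeds,
    flow_sign = 1,
    path_length_mm = path,
    chord_length_mm = chord,
    tortuosity = ifelse(chord > 0, path / chord, NA_real_))
  nrc <- ceiling(fov_mm[2] / roi_spacing_mm)
  ncc <- ceiling(fov_mm[1] / roi_spacing_mm)
  roi <- matrix(1L, nrc, ncc)
  attr(roi, "spacing_mm") <- roi_spacing_mm
  structure(list(
    segments = segments,
    fov_mm = fov_mm,
    roi_mask = roi,
    roi_spacing_mm = roi_spacing_mm,
    truth = list(
      total_length_mm = sum(path),
      mean_radius_mm = mean(radii),
      vessel_area_fraction = min(1, sum(path * 2 * radii) /
                                    (fov_mm[1] * fov_mm[2])),
      segment_speed_mm_s = speeds)),
    class = "vascular_phantom")
}

tree_centerlines <- function(depth, trunk_len, ratio, spread_deg, root,
                             root_angle_deg) {
  out <- list()
  recurse <- function(origin, angle, len, level) {
    if (level > depth) return(invisible())
    tip <- origin + len * c(cos(angle), sin(angle))
    out[[length(out) + 1L]] <<- cbind(
      x = seq(origin[1], tip[1], length.out = 25L),
      y = seq(origin[2], tip[2], length.out = 25L))
    half <- spread_deg * pi / 180
    recurse(tip, angle - half, len * ratio, level + 1L)
    recurse(tip, angle + half, len * ratio, level + 1L)
  }
  recurse(root, root_angle_deg * pi / 180, trunk_len, 1L)
  out
}

polyline_length <- function(cl) {
  d <- diff(cl)
  sum(sqrt(rowSums(d^2)))
}

#' @export
print.vascular_phantom <- function(x, ...) {
  cat(sprintf(
    "<vascular_phantom> %s: %d segment(s), FOV %.3g x %.3g mm, total length %.3g mm\n",
    x$kind %||% "custom", nrow(x$segments), x$fov_mm[1], x$fov_mm[2],
    x$truth$total_length_mm))
  invisible(x)
}
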