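#' Detect microbubbles in one CEUS frame at sub-pixel precision
#'
#' Candidate pixels are regional maxima (strictly greater than their
#' 8-neighborhood) above an intensity threshold; each candidate is refined to
#' the intensity-weighted centroid of the background-subtracted signal in a
#' square window. Duplicate detections closer than `window_px / 2` are merged,
#' keeping the brighter one. Detections whose nearest neighbor lies between
#' the merge radius and `isolation_px` are discarded in pairs: at such
#' separations two point-spread functions overlap partially and bias each
#' other's centroid, so neither position is trustworthy (the classical
#' sparse-bubble selection of ULM).
#'
#' @param frame numeric matrix (one CEUS frame), optionally with a
#'   `spacing_mm` attribute (see [get_frame()]).
#' @param threshold_mode `"mean_sd"` (threshold = frame mean + `k` * SD) or
#'   `"absolute"` (threshold = `k`).
#' @param k threshold parameter; default 4 background SDs.
#' @param window_px odd window width for centroid refinement.
#' @param isolation_px detections closer than this (but beyond the merge
#'   radius) are dropped pairwise; default `window_px`, `0` disables.
#' @param spacing_mm pixel pitch for the mm columns; taken from the frame
#'   attribute when `NULL`.
#' @return tibble with columns `x_px`, `y_px` (sub-pixel, column/row),
#'   `x_mm`, `y_mm`, `intensity`. Empty frame gives zero rows.
#' @examples
#' fr <- matrix(0, 32, 32)
#' fr[12:18, 12:18] <- outer(dnorm(-3:3), dnorm(-3:3))
#' detect_microbubbles(fr, spacing_mm = 0.1)
#' @export
detect_microbubbles <- function(frame, threshold_mode = c("mean_sd",
                                                          "absolute"),
                                k = 4, window_px = 11L,
                                isolation_px = window_px,
                                spacing_mm = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  spacing_mm <- spacing_mm %||% attr(frame, "spacing_mm") %||% 1
  res <- detect_core(frame, threshold_mode, k, window_px, isolation_px)
  tibble(
    x_px = res[, 1], y_px = res[, 2],
    x_mm = px_to_mm(res[, 1], spacing_mm),
    y_mm = px_to_mm(res[, 2], spacing_mm),
    intensity = res[, 3])
}

# matrix core of the detector: columns (x_px, y_px, intensity)
detect_core <- function(frame, threshold_mode, k, window_px, isolation_px) {
  stopifnot(all(is.finite(frame)))
  empty <- matrix(numeric(), 0L, 3L)
  nr <- nrow(frame); nc <- ncol(frame)
  if (nr < 3L || nc < 3L) return(empty)
  bg_mean <- mean(frame); bg_sd <- sd(frame)
  thr <- if (threshold_mode == "mean_sd") bg_mean + k * bg_sd else k

  inner <- frame[2:(nr - 1), 2:(nc - 1)]
  is_max <- inner > thr &
    inner > frame[1:(nr - 2), 2:(nc - 1)] &
    inner > frame[3:nr,       2:(nc - 1)] &
    inner > frame[2:(nr - 1), 1:(nc - 2)] &
    inner > frame[2:(nr - 1), 3:nc] &
    inner > frame[1:(nr - 2), 1:(nc - 2)] &
    inner > frame[1:(nr - 2), 3:nc] &
    inner > frame[3:nr,       1:(nc - 2)] &
    inner > frame[3:nr,       3:nc]
  cand <- which(is_max, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  cand <- cand + 1L  # back to full-frame indices

  half <- (as.integer(window_px) - 1L) %/% 2L
  res <- matrix(NA_real_, nrow(cand), 3L)
  for (i in seq_len(nrow(cand))) {
    r0 <- cand[i, 1]; c0 <- cand[i, 2]
    rs <- max(1L, r0 - half):min(nr, r0 + half)
    cs <- max(1L, c0 - half):min(nc, c0 + half)
    w <- pmax(frame[rs, cs, drop = FALSE] - bg_mean, 0)
    if (sum(w) <= 0) next
    res[i, ] <- c(sum(outer(rep(1, length(rs)), cs) * w) / sum(w),
                  sum(outer(rs, rep(1, length(cs))) * w) / sum(w),
                  frame[r0, c0])
  }
  ok <- !is.na(res[, 1])
  res <- res[ok, , drop = FALSE]
  if (!nrow(res)) return(empty)
  res <- merge_duplicates(res, min_sep = window_px / 2)
  if (isolation_px > window_px / 2 && nrow(res) > 1L) {
    d <- as.matrix(stats::dist(res[, 1:2, drop = FALSE]))
    diag(d) <- Inf
    res <- res[apply(d, 1, min) >= isolation_px, , drop = FALSE]
  }
  res
}

# res: columns (x_px, y_px, intensity); keep the brighter of any pair closer
# than min_sep px
merge_duplicates <- function(res, min_sep) {
  ord <- order(-res[, 3])
  res <- res[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!keep[i]) next
    if (i < nrow(res)) {
      j <- (i + 1L):nrow(res)
      d <- sqrt((res[j, 1] - res[i, 1])^2 + (res[j, 2] - res[i, 2])^2)
      keep[j][d < min_sep & keep[j]] <- FALSE
    }
  }
  res <- res[keep, , drop = FALSE]
  res[order(res[, 2], res[, 1]), , drop = FALSE]
}

#' Detect microbubbles across a whole sequence
#'
#' @param ceus a `frame_sequence` (motion-corrected CEUS).
#' @param background `"median"` (default) subtracts the per-pixel temporal
#'   median — the static background estimate — before detection, clamping at
#'   zero; `"none"` detects on the raw frames.
#' @inheritParams detect_microbubbles
#' @return tibble of localizations with a `frame` column, class
#'   `mb_localizations`; carries `frame_rate_hz` and `pixel_spacing_mm`
#'   attributes.
#' @export
detect_sequence <- function(ceus, threshold_mode = c("mean_sd", "absolute"), k = 4,
                            window_px = 11L, isolation_px = window_px,
                            background = c("median", "none")) {
  stopifnot(inherits(ceus, "frame_sequence"))
  background <- match.arg(background)
  frames <- ceus$frames
  if (background == "median" && dim(frames)[3] > 2L) {
    med <- apply(frames, c(1, 2), median)
    frames <- pmax(sweep(frames, c(1, 2), med, "-"), 0)
  }
  nfr <- n_frames(ceus)
  threshold_mode <- match.arg(threshold_mode, c("mean_sd", "absolute"))
  mats <- vector("list", nfr)
  for (f in seq_len(nfr)) {
    res <- detect_core(frames[, , f], threshold_mode, k, window_px,
                       isolation_px)
    if (nrow(res)) mats[[f]] <- cbind(f, res)
  }
  m <- do.call(rbind, mats[!vapply(mats, is.null, logical(1))])
  sp <- ceus$pixel_spacing_mm
  out <- if (is.null(m) || !nrow(m))
    tibble(frame = integer(), x_px = numeric(), y_px = numeric(),
           x_mm = numeric(), y_mm = numeric(), intensity = numeric())
  else
    tibble(frame = as.integer(m[, 1]), x_px = m[, 2], y_px = m[, 3],
           x_mm = px_to_mm(m[, 2], sp), y_mm = px_to_mm(m[, 3], sp),
           intensity = m[, 4])
  structure(out, class = c("mb_localizations", class(out)),
            frame_rate_hz = ceus$frame_rate_hz,
            pixel_spacing_mm = ceus$pixel_spacing_mm)
}

#' Link localizations into microbubble tracks
#'
#' Frame-to-frame matching by optimal bipartite assignment (Hungarian
#' algorithm) on Euclidean distance, gated at radius `v_max / frame_rate`.
#' Unmatched detections open new tracks; a track not extended for more than
#' `max_gap` frames is closed. Per-segment velocity is displacement times
#' frame rate (divided by the frame gap when coasting over gaps).
#'
#' @param localizations tibble from [detect_sequence()] (or any tibble with
#'   `frame`, `x_mm`, `y_mm`), with `frame_rate_hz` attribute or passed
#'   explicitly.
#' @param v_max gate speed in mm/s (> 0); default 15, five times typical
#'   testicular microvascular speeds (~3 mm/s). A much larger gate lets a
#'   track jump to a neighboring bubble when its own detection drops out for
#'   a frame, splicing fictitious fast segments into the velocity maps.
#' @param max_gap frames a track may coast unmatched (default 0: strictly
#'   consecutive).
#' @param frame_rate_hz,pixel_spacing_mm acquisition metadata; defaults from
#'   attributes of `localizations`.
#' @return tibble of class `mb_tracks`: `track_id`, `frame`, `x_mm`, `y_mm`,
#'   `vx_mm_s`, `vy_mm_s` (segment velocity from this localization to the
#'   next; `NA` on the last), ordered by track then frame.
#' @export
link_tracks <- function(localizations, v_max = 15, max_gap = 0L,
                        frame_rate_hz = NULL, pixel_spacing_mm = NULL) {
  if (v_max <= 0) abort("v_max must be > 0")
  frame_rate_hz <- frame_rate_hz %||% attr(localizations, "frame_rate_hz")
  pixel_spacing_mm <- pixel_spacing_mm %||%
    attr(localizations, "pixel_spacing_mm") %||% NA_real_
  if (is.null(frame_rate_hz))
    abort("frame_rate_hz unknown: pass it or use detect_sequence() output")
  loc <- as_tibble(localizations)[c("frame", "x_mm", "y_mm")]
  loc <- loc[order(loc$frame), ]
  gate <- v_max / frame_rate_hz  # mm per frame

  frames <- if (nrow(loc)) seq(min(loc$frame), max(loc$frame)) else integer()
  # active track state
  act_id <- integer(); act_x <- numeric(); act_y <- numeric()
  act_frame <- integer()
  next_id <- 1L
  rows <- vector("list", 0L)
  push <- function(id, frame, x, y)
    rows[[length(rows) + 1L]] <<- list(track_id = id, frame = frame,
                                       x_mm = x, y_mm = y)
  for (f in frames) {
    det <- loc[loc$frame == f, , drop = FALSE]
    # deterministic order: leftmost-topmost first
    det <- det[order(det$x_mm, det$y_mm), , drop = FALSE]
    matched_det <- rep(FALSE, nrow(det))
    if (length(act_id) && nrow(det)) {
      gap_fr <- f - act_frame
      cost <- outer(seq_along(act_id), seq_len(nrow(det)),
                    Vectorize(function(i, j)
                      sqrt((act_x[i] - det$x_mm[j])^2 +
                           (act_y[i] - det$y_mm[j])^2)))
      lim <- gate * gap_fr
      cost[cost > lim] <- Inf
      a <- solve_assignment(cost)
      for (i in seq_along(a)) {
        j <- a[i]
        if (is.na(j)) next
        push(act_id[i], f, det$x_mm[j], det$y_mm[j])
        act_x[i] <- det$x_mm[j]; act_y[i] <- det$y_mm[j]
        act_frame[i] <- f
        matched_det[j] <- TRUE
      }
    }
    # start new tracks from unmatched detections
    for (j in which(!matched_det)) {
      push(next_id, f, det$x_mm[j], det$y_mm[j])
      act_id <- c(act_id, next_id)
      act_x <- c(act_x, det$x_mm[j]); act_y <- c(act_y, det$y_mm[j])
      act_frame <- c(act_frame, f)
      next_id <- next_id + 1L
    }
    # retire tracks that have coasted too long
    alive <- (f - act_frame) <= max_gap
    act_id <- act_id[alive]; act_x <- act_x[alive]; act_y <- act_y[alive]
    act_frame <- act_frame[alive]
  }
  tr <- dplyr::bind_rows(rows)
  if (!nrow(tr))
    tr <- tibble(track_id = integer(), frame = integer(),
                 x_mm = numeric(), y_mm = numeric())
  tr <- dplyr::arrange(tr, .data$track_id, .data$frame)
  tr <- dplyr::group_by(tr, .data$track_id)
  tr <- dplyr::mutate(
    tr,
    vx_mm_s = (dplyr::lead(.data$x_mm) - .data$x_mm) /
      (dplyr::lead(.data$frame) - .data$frame) * frame_rate_hz,
    vy_mm_s = (dplyr::lead(.data$y_mm) - .data$y_mm) /
      (dplyr::lead(.data$frame) - .data$frame) * frame_rate_hz)
  tr <- dplyr::ungroup(tr)
  structure(tr, class = c("mb_tracks", class(tr)),
            frame_rate_hz = frame_rate_hz,
            pixel_spacing_mm = pixel_spacing_mm)
}

#' Smooth track coordinates with a short symmetric kernel
#'
#' Applies a [1/4, 1/2, 1/4] moving average (by default) to each track's
#' coordinates and recomputes the per-segment velocities from the smoothed
#' positions. This kernel nulls the two-frame alternation that merged
#' detections of near-coincident bubbles imprint on a trajectory, while
#' leaving the slow physical motion (a fraction of a pixel per frame)
#' essentially untouched. Endpoints use renormalized partial kernels.
#'
#' @param tracks an `mb_tracks` tibble.
#' @param kernel odd-length symmetric non-negative weights.
#' @return smoothed `mb_tracks` tibble.
#' @export
smooth_tracks <- function(tracks, kernel = c(0.25, 0.5, 0.25)) {
  stopifnot(length(kernel) %% 2L == 1L, all(kernel >= 0), sum(kernel) > 0)
  at <- attributes(tracks)
  fr <- at$frame_rate_hz
  if (is.null(fr)) abort("tracks must carry a frame_rate_hz attribute")
  r <- (length(kernel) - 1L) %/% 2L
  sm1 <- function(x) {
    n <- length(x)
    if (n <= 1L) return(x)
    vapply(seq_len(n), function(i) {
      idx <- max(1L, i - r):min(n, i + r)
      w <- kernel[idx - i + r + 1L]
      sum(x[idx] * w) / sum(w)
    }, numeric(1))
  }
  out <- dplyr::arrange(as_tibble(tracks), .data$track_id, .data$frame)
  out <- dplyr::group_by(out, .data$track_id)
  out <- dplyr::mutate(out, x_mm = sm1(.data$x_mm), y_mm = sm1(.data$y_mm))
  out <- dplyr::mutate(
    out,
    vx_mm_s = (dplyr::lead(.data$x_mm) - .data$x_mm) /
      (dplyr::lead(.data$frame) - .data$frame) * fr,
    vy_mm_s = (dplyr::lead(.data$y_mm) - .data$y_mm) /
      (dplyr::lead(.data$frame) - .data$frame) * fr)
  out <- dplyr::ungroup(out)
  structure(out, class = c("mb_tracks", class(out)),
            frame_rate_hz = fr, pixel_spacing_mm = at$pixel_spacing_mm)
}

#' Discard short tracks
#'
#' Tracks identified in fewer than `min_frames` frames are discarded to
#' suppress noise detections (default 3 frames).
#'
#' @param tracks an `mb_tracks` tibble.
#' @param min_frames minimum number of frames a track must span.
#' @return filtered `mb_tracks` tibble.
#' @export
filter_tracks <- function(tracks, min_frames = 3L) {
  at <- attributes(tracks)
  out <- dplyr::group_by(as_tibble(tracks), .data$track_id)
  out <- dplyr::filter(out, dplyr::n() >= min_frames)
  out <- dplyr::ungroup(out)
  structure(out, class = c("mb_tracks", class(out)),
            frame_rate_hz = at$frame_rate_hz,
            pixel_spacing_mm = at$pixel_spacing_mm)
}

#' Per-track summaries (path length, chord, duration, mean speed)
#'
#' @param tracks an `mb_tracks` tibble.
#' @return tibble, one row per track: `track_id`, `n_frames`,
#'   `path_length_mm`, `chord_length_mm`, `mean_speed_mm_s`.
#' @export
track_summary <- function(tracks) {
  tr <- dplyr::group_by(as_tibble(tracks), .data$track_id)
  dplyr::summarise(
    tr,
    n_frames = dplyr::n(),
    path_length_mm = sum(sqrt(diff(.data$x_mm)^2 + diff(.data$y_mm)^2)),
    chord_length_mm = sqrt((dplyr::last(.data$x_mm) -
                              dplyr::first(.data$x_mm))^2 +
                           (dplyr::last(.data$y_mm) -
                              dplyr::first(.data$y_mm))^2),
    mean_speed_mm_s = mean(sqrt(.data$vx_mm_s^2 + .data$vy_mm_s^2),
                           na.rm = TRUE),
    .groups = "drop")
}
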