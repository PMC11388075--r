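#' Suppress microbubble signal in B-mode by SVD truncation
#'
#' Reshapes the sequence into a Casorati matrix (pixels x frames), takes its
#' singular value decomposition and reconstructs from the `keep_rank` largest
#' singular components. Slowly varying tissue dominates the leading
#' components, while transiting microbubbles live in the smaller singular
#' values that are discarded — leaving a clean tissue sequence for motion
#' estimation.
#'
#' @param bmode a `frame_sequence` (B-mode channel).
#' @param keep_rank number of leading singular components to keep,
#'   `1 <= keep_rank <= n_frames`; `NULL` (default) keeps the smallest rank
#'   explaining at least `energy` of the total squared singular value mass.
#' @param energy energy fraction for the automatic rank rule. The default is
#'   deliberately high (0.999): the static tissue pattern holds almost all
#'   Casorati energy, and the tissue-motion components that registration
#'   needs live in the small tail just after it, while bubble transients sit
#'   further down still.
#' @return a `frame_sequence` of the same dimensions, with attributes
#'   `keep_rank` and `singular_values` on the returned object.
#' @examples
#' fs <- frame_sequence(array(rep(1, 4 * 4 * 5), c(4, 4, 5)), 0.1, 114)
#' out <- svd_suppress_bubbles(fs, keep_rank = 1)
#' @export
svd_suppress_bubbles <- function(bmode, keep_rank = NULL, energy = 0.999) {
  stopifnot(inherits(bmode, "frame_sequence"))
  d <- dim(bmode$frames)
  nfr <- d[3]
  cas <- matrix(bmode$frames, nrow = d[1] * d[2], ncol = nfr)
  sv <- svd(cas)
  if (is.null(keep_rank)) {
    e <- cumsum(sv$d^2) / sum(sv$d^2)
    keep_rank <- which(e >= energy)[1]
  }
  if (keep_rank < 1L || keep_rank > nfr)
    abort(sprintf("keep_rank must be in [1, %d], got %s", nfr, keep_rank))
  k <- seq_len(keep_rank)
  rec <- sv$u[, k, drop = FALSE] %*%
    (sv$d[k] * t(sv$v[, k, drop = FALSE]))
  out <- frame_sequence(array(rec, d), bmode$pixel_spacing_mm,
                        bmode$frame_rate_hz, bmode$channel)
  out$keep_rank <- as.integer(keep_rank)
  out$singular_values <- sv$d
  out
}

#' Two-stage tissue-motion estimation
#'
#' Stage 1 estimates a global per-frame translation against a reference frame
#' by phase correlation with local upsampled-DFT refinement (sub-pixel).
#' Stage 2 refines with coarse block-wise normalized cross-correlation over a
#' bounded integer search on the globally aligned frame, giving a coarse local
#' displacement grid. Frames with no signal fall back to stage 1 only (zero
#' local grid) with a warning.
#'
#' @param bmode_clean a `frame_sequence`, ideally after
#'   [svd_suppress_bubbles()].
#' @param reference_frame index of the reference; default the middle frame.
#' @param block_px stage-2 block size in pixels; `NA` skips stage 2.
#' @param search_px stage-2 integer search radius (px).
#' @param smooth_window width (frames) of the temporal Gaussian smoothing
#'   applied to the global translations (SD = `smooth_window / 4`).
#'   Physiological motion (breathing, probe drift) is slow against the frame
#'   rate, so smoothing suppresses per-frame estimation jitter without biasing
#'   the motion itself; `0` disables.
#' @return a `motion_field`: list with `global` (tibble `frame`, `dx_px`,
#'   `dy_px`), optional `local` (array `[frame, grid_row, grid_col, 2]` of
#'   residual displacements and the block center tables), and
#'   `reference_frame`.
#' @export
estimate_motion <- function(bmode_clean, reference_frame = NULL,
                            block_px = 16L, search_px = 3L,
                            smooth_window = 9L) {
  stopifnot(inherits(bmode_clean, "frame_sequence"))
  d <- dim(bmode_clean$frames)
  nfr <- d[3]
  if (is.null(reference_frame)) reference_frame <- (nfr + 1L) %/% 2L
  stopifnot(reference_frame >= 1L, reference_frame <= nfr)
  ref <- bmode_clean$frames[, , reference_frame]

  dx <- numeric(nfr); dy <- numeric(nfr)
  for (f in seq_len(nfr)) {
    if (f == reference_frame) next
    fr <- bmode_clean$frames[, , f]
    if (all(fr == 0)) {
      warn(sprintf("frame %d is all-zero; motion set to identity", f))
      next
    }
    sh <- phase_correlate(ref, fr)
    dy[f] <- sh[1]; dx[f] <- sh[2]
  }
  if (smooth_window > 0 && nfr > 2L) {
    dx <- smooth_series(dx, smooth_window)
    dy <- smooth_series(dy, smooth_window)
    # keep the reference frame at exact identity
    dx <- dx - dx[reference_frame]
    dy <- dy - dy[reference_frame]
  }
  global <- tibble(frame = seq_len(nfr), dx_px = dx, dy_px = dy)

  local <- NULL
  if (!is.na(block_px) && block_px > 0) {
    centers <- block_centers(d[1], d[2], block_px)
    larr <- array(0, c(nfr, nrow(centers$rc), 2L))
    for (f in seq_len(nfr)) {
      if (f == reference_frame) next
      fr <- bmode_clean$frames[, , f]
      if (all(fr == 0)) next
      aligned <- shift_image(fr, -dx[f], -dy[f])
      larr[f, , ] <- block_refine(ref, aligned, centers, block_px, search_px)
    }
    local <- list(displacement = larr, centers = centers$rc,
                  block_px = as.integer(block_px))
  }
  structure(list(global = global, local = local,
                 reference_frame = as.integer(reference_frame)),
            class = "motion_field")
}

#' @export
print.motion_field <- function(x, ...) {
  cat(sprintf("<motion_field> %d frames, reference %d, %s local grid\n",
              nrow(x$global), x$reference_frame,
              if (is.null(x$local)) "no" else
                sprintf("%d-block", nrow(x$local$centers))))
  invisible(x)
}

#' Tidy a motion field into a per-frame tibble
#' @param x a `motion_field`.
#' @param ... unused.
#' @return tibble `frame`, `dx_px`, `dy_px`.
#' @importFrom generics tidy
#' @method tidy motion_field
#' @export
tidy.motion_field <- function(x, ...) x$global

# phase correlation shift of `img` relative to `ref` (content displacement
# (dy, dx) such that img ~ ref shifted by (dy, dx)), with local upsampled-DFT
# refinement to ~1/50 px
phase_correlate <- function(ref, img, upsample = 50L) {
  nr0 <- nrow(ref); nc0 <- ncol(ref)
  # Hann window: suppresses the wrap-around discontinuity of the DFT for
  # non-periodic fields, which otherwise biases the whitened spectrum
  wr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nr0) - 1) / (nr0 - 1))
  wc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nc0) - 1) / (nc0 - 1))
  w <- outer(wr, wc)
  ref <- (ref - mean(ref)) * w
  img <- (img - mean(img)) * w
  F1 <- fft(ref); F2 <- fft(img)
  R <- F1 * Conj(F2)
  # regularized whitening + half-Nyquist low-pass: plain phase correlation
  # amplifies the incoherent high frequencies introduced by resampling
  nr <- nrow(ref); nc <- ncol(ref)
  Rn <- R / (Mod(R) + 0.01 * max(Mod(R)))
  krf <- ifelse(seq_len(nr) - 1 > nr / 2,
                seq_len(nr) - 1 - nr, seq_len(nr) - 1) / nr
  kcf <- ifelse(seq_len(nc) - 1 > nc / 2,
                seq_len(nc) - 1 - nc, seq_len(nc) - 1) / nc
  Rn <- Rn * outer(abs(krf) <= 0.25, abs(kcf) <= 0.25)
  cc <- Re(fft(Rn, inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  sh <- c(pk[1] - 1L, pk[2] - 1L)
  sh[1] <- if (sh[1] > nr / 2) sh[1] - nr else sh[1]
  sh[2] <- if (sh[2] > nc / 2) sh[2] - nc else sh[2]
  # refine around -sh by evaluating the cross-correlation on an upsampled
  # local grid via explicit DFT sums (matrix-multiply DFT)
  win <- 1.5
  dr <- seq(sh[1] - win, sh[1] + win, by = 1 / upsample)
  dc <- seq(sh[2] - win, sh[2] + win, by = 1 / upsample)
  kr <- 2 * pi * krf
  kc <- 2 * pi * kcf
  Er <- exp(1i * outer(dr, kr))        # |dr| x nr
  Ec <- exp(1i * outer(kc, dc))        # nc x |dc|
  cc2 <- Re(Er %*% Rn %*% Ec)
  pk2 <- which(cc2 == max(cc2), arr.ind = TRUE)[1, ]
  -c(dr[pk2[1]], dc[pk2[2]])
}

# Gaussian-weighted temporal smoothing with edge renormalization
smooth_series <- function(x, window) {
  sd <- window / 4
  r <- ceiling(2 * sd)
  k <- dnorm(seq(-r, r), sd = sd)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    idx <- max(1L, i - r):min(n, i + r)
    w <- k[idx - i + r + 1L]
    sum(x[idx] * w) / sum(w)
  }, numeric(1))
}

block_centers <- function(nr, nc, block) {
  rs <- seq(1L + block %/% 2L, nr - block %/% 2L, by = block)
  cs <- seq(1L + block %/% 2L, nc - block %/% 2L, by = block)
  if (!length(rs)) rs <- nr %/% 2L
  if (!length(cs)) cs <- nc %/% 2L
  list(rc = as.matrix(expand.grid(row = rs, col = cs)))
}

# per-block residual displacement by windowed phase correlation, bounded by
# the search radius (larger apparent shifts are distrusted and zeroed)
block_refine <- function(ref, aligned, centers, block, search) {
  half <- block %/% 2L
  out <- matrix(0, nrow(centers$rc), 2L)
  for (b in seq_len(nrow(centers$rc))) {
    r0 <- centers$rc[b, 1]; c0 <- centers$rc[b, 2]
    rs <- (r0 - half):(r0 + half - 1L)
    cs <- (c0 - half):(c0 + half - 1L)
    patch <- aligned[rs, cs]
    refp <- ref[rs, cs]
    if (sd(patch) < 1e-12 || sd(refp) < 1e-12) next
    sh <- phase_correlate(refp, patch, upsample = 20L)
    if (max(abs(sh)) <= search) out[b, ] <- sh
  }
  out
}

#' Apply a motion correction to a CEUS sequence
#'
#' Resamples each frame by the inverse of its estimated transform (global
#' translation plus, when present, the bilinearly interpolated coarse local
#' displacement field), with bilinear interpolation and zero fill outside the
#' field of view. The corrected sequence has all frames in the reference-frame
#' coordinate system.
#'
#' @param ceus a `frame_sequence`.
#' @param motion a `motion_field` with the same number of frames.
#' @return corrected `frame_sequence`.
#' @export
apply_motion_correction <- function(ceus, motion) {
  stopifnot(inherits(ceus, "frame_sequence"),
            inherits(motion, "motion_field"))
  d <- dim(ceus$frames)
  if (nrow(motion$global) != d[3])
    abort(sprintf("motion has %d frames but sequence has %d",
                  nrow(motion$global), d[3]))
  out <- ceus$frames
  for (f in seq_len(d[3])) {
    dx <- motion$global$dx_px[f]; dy <- motion$global$dy_px[f]
    if (is.null(motion$local)) {
      if (dx == 0 && dy == 0) next
      out[, , f] <- shift_image(ceus$frames[, , f], -dx, -dy)
    } else {
      disp <- dense_local_field(motion, f, d[1], d[2])
      rr <- matrix(seq_len(d[1]), d[1], d[2]) + dy + disp[, , 1]
      cc <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) + dx + disp[, , 2]
      out[, , f] <- bilinear_sample(ceus$frames[, , f], rr, cc)
    }
  }
  frame_sequence(out, ceus$pixel_spacing_mm, ceus$frame_rate_hz,
                 ceus$channel)
}

# bilinear upsample of the coarse block grid to a dense (dy, dx) field
dense_local_field <- function(motion, f, nr, nc) {
  ctr <- motion$local$centers
  disp <- motion$local$displacement[f, , , drop = FALSE]
  rs <- sort(unique(ctr[, 1])); cs <- sort(unique(ctr[, 2]))
  out <- array(0, c(nr, nc, 2L))
  for (k in 1:2) {
    g <- matrix(0, length(rs), length(cs))
    g[cbind(match(ctr[, 1], rs), match(ctr[, 2], cs))] <- disp[1, , k]
    if (length(rs) == 1L && length(cs) == 1L) {
      out[, , k] <- g[1, 1]
    } else {
      ri <- pmin(pmax((seq_len(nr) - rs[1]) /
                        max(1, diff(range(rs))) * (length(rs) - 1) + 1,
                      1), length(rs))
      ci <- pmin(pmax((seq_len(nc) - cs[1]) /
                        max(1, diff(range(cs))) * (length(cs) - 1) + 1,
                      1), length(cs))
      out[, , k] <- bilinear_sample(g, matrix(ri, nr, nc),
                                    matrix(ci, nr, nc, byrow = TRUE))
    }
  }
  out
}
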