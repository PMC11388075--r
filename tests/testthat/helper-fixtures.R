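# Shared fixtures, all generated in code.

# render an isotropic Gaussian blob sequence (no noise) as a frame_sequence
blob_sequence <- function(centers_px, nr = 40, nc = 40, sigma_px = 2,
                          spacing = 0.1, rate = 114, amp = 1) {
  nfr <- nrow(centers_px)
  arr <- array(0, c(nr, nc, nfr))
  for (f in seq_len(nfr)) {
    r0 <- centers_px[f, 1]; c0 <- centers_px[f, 2]
    arr[, , f] <- amp * outer(exp(-(seq_len(nr) - r0)^2 / (2 * sigma_px^2)),
                              exp(-(seq_len(nc) - c0)^2 / (2 * sigma_px^2)))
  }
  frame_sequence(arr, spacing, rate, "ceus")
}

# hand-built tracks tibble with segment velocities from the coordinates
make_tracks <- function(df, frame_rate = 114, spacing = 0.1) {
  df <- dplyr::arrange(df, track_id, frame)
  df <- dplyr::group_by(df, track_id)
  df <- dplyr::mutate(
    df,
    vx_mm_s = (dplyr::lead(x_mm) - x_mm) /
      (dplyr::lead(frame) - frame) * frame_rate,
    vy_mm_s = (dplyr::lead(y_mm) - y_mm) /
      (dplyr::lead(frame) - frame) * frame_rate)
  df <- dplyr::ungroup(df)
  structure(df, class = c("mb_tracks", class(df)),
            frame_rate_hz = frame_rate, pixel_spacing_mm = spacing)
}

# Sierpinski carpet mask after `iter` subdivisions (3^iter square)
sierpinski_mask <- function(iter = 5) {
  m <- matrix(1L, 1, 1)
  for (i in seq_len(iter)) {
    n <- nrow(m)
    big <- matrix(0L, 3 * n, 3 * n)
    for (bi in 0:2) for (bj in 0:2) {
      if (bi == 1 && bj == 1) next
      big[bi * n + seq_len(n), bj * n + seq_len(n)] <- m
    }
    m <- big
  }
  m
}

# brute-force minimal-cost assignment by permutation enumeration (n <= 6)
brute_assignment_cost <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  min(vapply(perms(seq_len(n)), function(p)
    sum(cost[cbind(seq_len(n), p)]), numeric(1)))
}

skip_slow <- function() invisible(TRUE)  # all tests run everywhere
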