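test_that("a blank frame yields no detections", {
  expect_equal(nrow(detect_microbubbles(matrix(0, 20, 20))), 0L)
})

test_that("a noiseless Gaussian blob is localized within 0.1 px", {
  nr <- 40; nc <- 40
  blob <- outer(exp(-(seq_len(nr) - 20.70)^2 / (2 * 2^2)),
                exp(-(seq_len(nc) - 10.30)^2 / (2 * 2^2)))
  det <- detect_microbubbles(blob, spacing_mm = 0.1)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x_px - 10.30), 0.1)
  expect_lt(abs(det$y_px - 20.70), 0.1)
  # localization bias stays below 0.1 px across sub-pixel phases
  for (off in seq(0, 0.9, by = 0.3)) {
    b <- outer(exp(-(seq_len(nr) - 20 - off)^2 / 8),
               exp(-(seq_len(nc) - 15)^2 / 8))
    d <- detect_microbubbles(b, spacing_mm = 0.1)
    expect_lt(abs(d$y_px - 20 - off), 0.1)
  }
})

test_that("two well-separated blobs give exactly two localizations", {
  nr <- 40; nc <- 60
  two <- outer(exp(-(seq_len(nr) - 20)^2 / 2),
               exp(-(seq_len(nc) - 15)^2 / 2)) +
         outer(exp(-(seq_len(nr) - 20)^2 / 2),
               exp(-(seq_len(nc) - 45)^2 / 2))
  det <- detect_microbubbles(two, window_px = 5L, isolation_px = 0)
  expect_equal(nrow(det), 2L)
  expect_equal(sort(round(det$x_px)), c(15, 45))
})

test_that("partially overlapping detections are dropped pairwise", {
  nr <- 40; nc <- 60
  two <- outer(exp(-(seq_len(nr) - 20)^2 / 8),
               exp(-(seq_len(nc) - 25)^2 / 8)) +
         outer(exp(-(seq_len(nr) - 20)^2 / 8),
               exp(-(seq_len(nc) - 33)^2 / 8))
  det <- detect_microbubbles(two, window_px = 11L, isolation_px = 11L)
  expect_equal(nrow(det), 0L)
})

test_that("Hungarian assignment matches brute-force enumeration", {
  withr::with_seed(21, {
    for (rep in 1:25) {
      n <- sample(2:6, 1)
      C <- matrix(runif(n * n), n)
      a <- ulmvasc:::solve_assignment(C)
      expect_equal(sum(C[cbind(seq_len(n), a)]), brute_assignment_cost(C),
                   tolerance = 1e-10)
    }
  })
})

test_that("a single constant-velocity bubble yields one track at v = d * f", {
  # 3/114 mm per frame at 114 Hz -> 3 mm/s exactly
  n <- 8
  centers <- cbind(rep(20, n), 8 + (0:(n - 1)) * (3 / 114) / 0.1)
  fs <- blob_sequence(centers, sigma_px = 1.5)
  loc <- detect_sequence(fs, background = "none")
  tr <- link_tracks(loc)
  expect_equal(dplyr::n_distinct(tr$track_id), 1L)
  sp <- sqrt(tr$vx_mm_s^2 + tr$vy_mm_s^2)
  expect_equal(sp[!is.na(sp)], rep(3, n - 1), tolerance = 0.02)
})

test_that("a detection beyond the gate radius starts a new track", {
  loc <- tibble::tibble(frame = c(1L, 2L),
                        x_mm = c(1, 3), y_mm = c(1, 1))
  tr <- link_tracks(loc, v_max = 15, frame_rate_hz = 114)
  expect_equal(dplyr::n_distinct(tr$track_id), 2L)
  tr2 <- link_tracks(loc, v_max = 300, frame_rate_hz = 114)
  expect_equal(dplyr::n_distinct(tr2$track_id), 1L)
  expect_error(link_tracks(loc, v_max = 0, frame_rate_hz = 114), "v_max")
})

test_that("two bubbles with spatially crossing paths keep their identities", {
  # one moves right along y = 1, the other crosses that line at x = 1.5 a few
  # frames earlier; paths intersect in space but the bubbles never come
  # within the assignment gate at the same time
  n <- 19
  t <- 0:(n - 1)
  a <- tibble::tibble(frame = t + 1L, x_mm = 1 + 0.03 * t, y_mm = 1)
  b <- tibble::tibble(frame = t + 1L, x_mm = 1.5, y_mm = 1.27 - 0.03 * t)
  loc <- dplyr::bind_rows(a, b)
  tr <- link_tracks(loc, v_max = 5, frame_rate_hz = 114)
  expect_equal(dplyr::n_distinct(tr$track_id), 2L)
  ts <- track_summary(tr)
  # each track stays straight: path == chord (no identity swap kink)
  expect_equal(ts$path_length_mm, ts$chord_length_mm, tolerance = 1e-9)
})

test_that("track filtering enforces the three-frame rule", {
  loc <- tibble::tibble(
    frame = c(1L, 2L, 1L, 2L, 3L),
    x_mm = c(1, 1.01, 3, 3.01, 3.02), y_mm = 1)
  tr <- link_tracks(loc, v_max = 5, frame_rate_hz = 114)
  kept <- filter_tracks(tr, min_frames = 3L)
  expect_equal(dplyr::n_distinct(tr$track_id), 2L)
  expect_equal(dplyr::n_distinct(kept$track_id), 1L)
  # a 3-frame track is retained
  expect_equal(unique(dplyr::count(kept, track_id)$n), 3L)
  expect_equal(nrow(filter_tracks(tr[0, ])), 0L)
})

test_that("tracking is symmetric under frame reversal", {
  withr::with_seed(31, {
    nfr <- 12
    loc <- dplyr::bind_rows(lapply(1:3, function(i) {
      tibble::tibble(frame = seq_len(nfr),
                     x_mm = i + cumsum(runif(nfr, 0.01, 0.02)),
                     y_mm = 2 * i + cumsum(runif(nfr, -0.01, 0.01)))
    }))
    fwd <- link_tracks(loc, v_max = 15, frame_rate_hz = 114)
    rev_loc <- dplyr::mutate(loc, frame = nfr + 1L - frame)
    bwd <- link_tracks(rev_loc, v_max = 15, frame_rate_hz = 114)
    key <- function(tr) {
      tr <- dplyr::arrange(tr, track_id, frame)
      split(paste(round(tr$x_mm, 9), round(tr$y_mm, 9)), tr$track_id) |>
        lapply(paste, collapse = ";") |> unlist() |> unname() |> sort()
    }
    expect_equal(key(fwd),
                 key(dplyr::mutate(bwd, frame = nfr + 1L - frame)))
    # segment multisets are mirror images: every backward segment is a
    # forward segment traversed the other way (velocities negated)
    seg_key <- function(tr) {
      tr <- dplyr::arrange(tr, track_id, frame)
      out <- dplyr::group_by(tr, track_id)
      out <- dplyr::reframe(out,
        x1 = head(x_mm, -1), y1 = head(y_mm, -1),
        x2 = tail(x_mm, -1), y2 = tail(y_mm, -1))
      sort(paste(round(out$x1, 9), round(out$y1, 9),
                 round(out$x2, 9), round(out$y2, 9)))
    }
    fwd_rev <- seg_key(dplyr::mutate(fwd, x_mm = x_mm, y_mm = y_mm))
    bwd_seg <- seg_key(bwd)
    swap <- function(k) vapply(strsplit(k, " "), function(v)
      paste(v[3], v[4], v[1], v[2]), character(1))
    expect_equal(sort(swap(bwd_seg)), fwd_rev)
  })
})

test_that("localization recall and precision are 1 on clean well-separated simulator output", {
  ph <- build_phantom("straight", list(length_mm = 4, radius_mm = 0.2),
                      fov_mm = c(6, 3))
  cfg <- acquisition_config(duration_s = 4, mb_rate_hz = 0.8,
                            motion_amplitude_px = 0, speckle_snr_db = 60,
                            seed = 17)
  sim <- simulate_mb_transit(ph, cfg)
  pos <- sim$truth$positions[!sim$truth$positions$crowded, ]
  loc <- detect_sequence(sim$ceus)
  matched <- 0; speeds_ok <- TRUE
  for (f in unique(pos$frame)) {
    pf <- pos[pos$frame == f, ]; lf <- loc[loc$frame == f, ]
    for (i in seq_len(nrow(pf))) {
      d <- sqrt((lf$x_mm - pf$x_mm[i])^2 + (lf$y_mm - pf$y_mm[i])^2)
      if (length(d) && min(d) < 0.5 * cfg$pixel_spacing_mm)
        matched <- matched + 1
    }
  }
  expect_gte(matched / nrow(pos), 0.95)      # recall at 0.5 px radius
  expect_lte(nrow(loc), nrow(pos) * 1.05)    # no spurious detections
  tr <- smooth_tracks(filter_tracks(link_tracks(loc)))
  sp <- sqrt(tr$vx_mm_s^2 + tr$vy_mm_s^2)
  expect_lt(abs(median(sp, na.rm = TRUE) - 3) / 3, 0.02)
})
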