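speckle_field <- function(nr = 48, nc = 48, seed = 2) {
  withr::with_seed(seed, ulmvasc:::gauss_blur(matrix(runif(nr * nc), nr), 1.5))
}

test_that("full-rank SVD reconstruction is the identity; rank-1 is exact for a static stack", {
  img <- speckle_field()
  static <- frame_sequence(array(rep(img, 6), c(dim(img), 6)), 0.1, 114)
  r1 <- svd_suppress_bubbles(static, keep_rank = 1)
  expect_equal(r1$frames, static$frames, tolerance = 1e-8)
  # varying stack, full rank = identity
  arr <- withr::with_seed(4, array(runif(12 * 12 * 5), c(12, 12, 5)))
  fs <- frame_sequence(arr, 0.1, 114)
  rf <- svd_suppress_bubbles(fs, keep_rank = 5)
  expect_equal(rf$frames, fs$frames, tolerance = 1e-10)
  expect_error(svd_suppress_bubbles(fs, keep_rank = 9), "keep_rank")
})

test_that("discarded energy equals the sum of squared dropped singular values", {
  arr <- withr::with_seed(5, array(runif(10 * 10 * 6), c(10, 10, 6)))
  fs <- frame_sequence(arr, 0.1, 114)
  out <- svd_suppress_bubbles(fs, keep_rank = 2)
  resid <- sum((fs$frames - out$frames)^2)
  expect_equal(resid, sum(out$singular_values[3:6]^2), tolerance = 1e-8)
})

test_that("rank truncation removes moving blobs from a static background", {
  img <- speckle_field()
  nfr <- 10
  arr <- array(rep(img, nfr), c(dim(img), nfr))
  blob_px <- matrix(NA_real_, nfr, 2)
  for (f in seq_len(nfr)) {
    r0 <- 10 + 2.5 * f
    blob_px[f, ] <- c(r0, 24)
    arr[, , f] <- arr[, , f] +
      2 * outer(exp(-(seq_len(48) - r0)^2 / 8),
                exp(-(seq_len(48) - 24)^2 / 8))
  }
  fs <- frame_sequence(arr, 0.1, 114)
  out <- svd_suppress_bubbles(fs, keep_rank = 1)
  # energy in blob pixels relative to the clean static background
  blob_energy <- function(a) {
    e <- 0
    for (f in seq_len(nfr)) {
      rs <- round(blob_px[f, 1]) + (-2:2)
      e <- e + sum((a[rs, 22:26, f] - img[rs, 22:26])^2)
    }
    e
  }
  expect_lt(blob_energy(out$frames), 0.1 * blob_energy(fs$frames))
})

test_that("an injected pure shift is recovered within 0.1 px per frame", {
  img <- speckle_field()
  shifts <- rbind(c(0, 0), c(2.5, -1.25), c(-1.5, 0.75), c(1, 2))
  arr <- array(0, c(dim(img), nrow(shifts)))
  for (f in seq_len(nrow(shifts)))
    arr[, , f] <- ulmvasc:::shift_image(img, shifts[f, 1], shifts[f, 2])
  fs <- frame_sequence(arr, 0.1, 114)
  mo <- estimate_motion(fs, reference_frame = 1L, block_px = NA,
                        smooth_window = 0)
  td <- tidy(mo)
  expect_equal(td$dx_px, shifts[, 1], tolerance = 0.1)
  expect_equal(td$dy_px, shifts[, 2], tolerance = 0.1)
})

test_that("identical frames give identity motion; all-zero frames warn", {
  img <- speckle_field()
  fs <- frame_sequence(array(rep(img, 4), c(dim(img), 4)), 0.1, 114)
  mo <- estimate_motion(fs, block_px = NA)
  expect_true(all(abs(tidy(mo)$dx_px) < 1e-6))
  expect_true(all(abs(tidy(mo)$dy_px) < 1e-6))
  arr <- array(rep(img, 3), c(dim(img), 3))
  arr[, , 3] <- 0
  fs0 <- frame_sequence(arr, 0.1, 114)
  expect_warning(estimate_motion(fs0, reference_frame = 1L, block_px = NA),
                 "all-zero")
})

test_that("motion estimation is shift-equivariant within 0.1 px", {
  img <- speckle_field()
  base <- c(1.2, -0.8)
  delta <- c(0.6, 0.9)
  arr <- array(0, c(dim(img), 2))
  arr[, , 1] <- img
  arr[, , 2] <- ulmvasc:::shift_image(img, base[1], base[2])
  fs <- frame_sequence(arr, 0.1, 114)
  m1 <- tidy(estimate_motion(fs, reference_frame = 1L, block_px = NA,
                             smooth_window = 0))
  arr2 <- arr
  arr2[, , 2] <- ulmvasc:::shift_image(img, base[1] + delta[1],
                                       base[2] + delta[2])
  fs2 <- frame_sequence(arr2, 0.1, 114)
  m2 <- tidy(estimate_motion(fs2, reference_frame = 1L, block_px = NA,
                             smooth_window = 0))
  expect_equal(m2$dx_px[2] - m1$dx_px[2], delta[1], tolerance = 0.1)
  expect_equal(m2$dy_px[2] - m1$dy_px[2], delta[2], tolerance = 0.1)
})

test_that("stage 2 shrinks the residual of a local bulge by at least half", {
  img <- speckle_field()
  nr <- nrow(img); nc <- ncol(img)
  # local bulge: 1 px displacement confined to one quadrant, zero elsewhere
  wr <- exp(-((matrix(seq_len(nr), nr, nc) - 12)^2 +
                (matrix(seq_len(nc), nr, nc, byrow = TRUE) - 12)^2) / 200)
  rr <- matrix(seq_len(nr), nr, nc) - 1 * wr
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  warped <- ulmvasc:::bilinear_sample(img, rr, cc)
  arr <- array(0, c(nr, nc, 2)); arr[, , 1] <- img; arr[, , 2] <- warped
  fs <- frame_sequence(arr, 0.1, 114)
  mo1 <- estimate_motion(fs, reference_frame = 1L, block_px = NA,
                         smooth_window = 0)
  mo2 <- estimate_motion(fs, reference_frame = 1L, block_px = 12L,
                         smooth_window = 0)
  res1 <- sum((apply_motion_correction(fs, mo1)$frames[5:44, 5:44, 2] -
                 img[5:44, 5:44])^2)
  res2 <- sum((apply_motion_correction(fs, mo2)$frames[5:44, 5:44, 2] -
                 img[5:44, 5:44])^2)
  expect_lt(res2, 0.5 * res1)
})

test_that("identity motion correction returns the input exactly", {
  arr <- withr::with_seed(6, array(runif(20 * 20 * 3), c(20, 20, 3)))
  fs <- frame_sequence(arr, 0.1, 114)
  mo <- structure(list(global = tibble::tibble(frame = 1:3, dx_px = 0,
                                               dy_px = 0),
                       local = NULL, reference_frame = 2L),
                  class = "motion_field")
  expect_identical(apply_motion_correction(fs, mo)$frames, fs$frames)
  mo_bad <- structure(list(global = tibble::tibble(frame = 1:2, dx_px = 0,
                                                   dy_px = 0),
                           local = NULL, reference_frame = 1L),
                      class = "motion_field")
  expect_error(apply_motion_correction(fs, mo_bad), "frames")
})

test_that("a known shift round-trips through the inverse resampling", {
  seq0 <- blob_sequence(cbind(c(20, 20, 20), c(15, 15, 15)))
  arr <- seq0$frames
  arr[, , 2] <- ulmvasc:::shift_image(arr[, , 2], 1.6, -2.2)
  fs <- frame_sequence(arr, 0.1, 114)
  mo <- structure(list(
    global = tibble::tibble(frame = 1:3, dx_px = c(0, 1.6, 0),
                            dy_px = c(0, -2.2, 0)),
    local = NULL, reference_frame = 1L), class = "motion_field")
  corr <- apply_motion_correction(fs, mo)
  for (f in 1:3) {
    det <- detect_microbubbles(corr$frames[, , f], spacing_mm = 0.1)
    expect_equal(nrow(det), 1L)
    expect_lt(abs(det$x_px - 15), 0.1)
    expect_lt(abs(det$y_px - 20), 0.1)
  }
})
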