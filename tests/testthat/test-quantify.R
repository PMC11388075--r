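test_that("half-peak binarization: zero density, band growth, monotonicity", {
  g <- sr_grid(30, 30, 0.1, 4L)
  zero <- matrix(0, 120, 120)
  attr(zero, "blur_sd") <- 1
  expect_true(all(binarize_vessels(zero) == 0))

  one <- make_tracks(tibble::tibble(track_id = 1L, frame = 1:2,
                                    x_mm = c(0.5, 2.5), y_mm = 1.5))
  widths <- vapply(c(1, 2, 3), function(sd) {
    d <- accumulate_density(one, g, sd)
    m <- binarize_vessels(d, sd)
    sum(m[, 60])  # band width at a mid column
  }, numeric(1))
  # analytic half-maximum band of a blurred line: ~2 * 1.177 * sd + 1
  expect_equal(widths, 2 * 1.177 * c(1, 2, 3) + 1, tolerance = 0.35 * 3)
  expect_true(all(diff(widths) > 0))

  # doubling counts never shrinks the mask
  two <- make_tracks(tibble::tibble(track_id = c(1L, 1L, 2L, 2L),
                                    frame = c(1:2, 1:2),
                                    x_mm = c(0.5, 2.5, 0.5, 2.5),
                                    y_mm = 1.5))
  m1 <- binarize_vessels(accumulate_density(one, g, 2), 2)
  m2 <- binarize_vessels(accumulate_density(two, g, 2), 2)
  expect_true(all(m2 >= m1))
})

test_that("thinning gives one-pixel centerlines inside the mask, preserving components", {
  mask <- matrix(0L, 40, 60)
  mask[18:25, 5:55] <- 1L            # horizontal bar
  mask[5:10, 10:20] <- 1L            # disjoint blob
  sk <- centerlines(mask)
  expect_true(all(sk[mask == 0] == 0))        # skeleton subset of mask
  lab_m <- EBImage::bwlabel(mask)
  lab_s <- EBImage::bwlabel(sk)
  expect_equal(max(lab_s), max(lab_m))        # same component count
  # bar reduces to a single-pixel-thick line
  bar_cols <- 30:40
  expect_true(all(colSums(sk[, bar_cols]) == 1))
})

test_that("diameters from the distance transform match strip and disc oracles", {
  g <- sr_grid(25, 25, 0.1, 4L)  # sr spacing 0.025 mm
  strip <- matrix(0L, 100, 100)
  strip[47:54, 10:90] <- 1L  # 8 px wide
  sk <- centerlines(strip)
  vd <- vessel_diameters(sk, strip, g)
  interior <- vd$diameters_um
  expect_equal(mean(interior) / (0.025 * 1000), 8, tolerance = 0.15)

  disc <- matrix(0L, 100, 100)
  rr <- row(disc) - 50; cc <- col(disc) - 50
  disc[rr^2 + cc^2 <= 20^2] <- 1L
  skd <- centerlines(disc)
  vdd <- vessel_diameters(skd, disc, g)
  expect_equal(max(vdd$diameters_um) / (0.025 * 1000), 40, tolerance = 0.08)

  # doubling the grid spacing doubles reported micrometers
  g2 <- sr_grid(25, 25, 0.2, 4L)
  vd2 <- vessel_diameters(sk, strip, g2)
  expect_equal(vd2$mean_diameter_um, 2 * vd$mean_diameter_um,
               tolerance = 1e-12)
  # empty skeleton reports missing
  expect_true(is.na(vessel_diameters(matrix(0L, 4, 4), matrix(1L, 4, 4),
                                     g)$mean_diameter_um))
})

test_that("tortuosity: straight, semicircle, right angle, and invariances", {
  straight <- make_tracks(tibble::tibble(track_id = 1L, frame = 1:3,
                                         x_mm = c(1, 2, 3), y_mm = 1))
  expect_equal(track_tortuosity(straight)$mean_tortuosity, 1,
               tolerance = 1e-12)

  th <- seq(0, pi, length.out = 400)
  semi <- make_tracks(tibble::tibble(track_id = 1L, frame = seq_along(th),
                                     x_mm = 3 + 2 * cos(th),
                                     y_mm = 3 + 2 * sin(th)))
  expect_equal(track_tortuosity(semi)$mean_tortuosity, pi / 2,
               tolerance = 0.001)

  ra <- make_tracks(tibble::tibble(track_id = 1L, frame = 1:3,
                                   x_mm = c(0, 3, 3), y_mm = c(0, 0, 4)))
  expect_equal(track_tortuosity(ra)$mean_tortuosity, 7 / 5,
               tolerance = 1e-12)

  # rotation + scaling invariance
  phi <- 0.7; s <- 2.3
  rot <- make_tracks(tibble::tibble(
    track_id = 1L, frame = 1:3,
    x_mm = s * (c(0, 3, 3) * cos(phi) - c(0, 0, 4) * sin(phi)) + 5,
    y_mm = s * (c(0, 3, 3) * sin(phi) + c(0, 0, 4) * cos(phi)) + 5))
  expect_equal(track_tortuosity(rot)$mean_tortuosity, 7 / 5,
               tolerance = 1e-9)

  # zero-chord track excluded with a tally
  loopy <- make_tracks(tibble::tibble(track_id = c(1L, 1L, 1L),
                                      frame = 1:3,
                                      x_mm = c(1, 2, 1), y_mm = c(1, 1, 1)))
  tt <- track_tortuosity(loopy)
  expect_equal(tt$n_excluded_zero_chord, 1L)
  expect_true(is.na(tt$mean_tortuosity))
})

test_that("box-counting fractal number matches line, plane and Sierpinski oracles", {
  n <- 256
  line <- matrix(0L, n, n); line[128, ] <- 1L
  fl <- fractal_number(line)
  expect_lt(abs(fl$fractal_number - 1), 0.1)

  rect <- matrix(1L, n, n)
  fr <- fractal_number(rect)
  expect_lt(abs(fr$fractal_number - 2), 0.1)

  carpet <- sierpinski_mask(5)  # 243 x 243
  fc <- fractal_number(carpet, box_sizes = c(81L, 27L, 9L, 3L, 1L))
  expect_lt(abs(fc$fractal_number - log(8) / log(3)), 0.05)

  # translation invariance
  line2 <- matrix(0L, n, n); line2[40, ] <- 1L
  expect_equal(fractal_number(line2)$fractal_number, fl$fractal_number,
               tolerance = 1e-12)
  # 90 degree rotation within 0.05
  expect_lt(abs(fractal_number(t(line))$fractal_number - fl$fractal_number),
            0.05)
  expect_error(fractal_number(matrix(0L, 8, 8)), "empty")
  expect_error(fractal_number(line, box_sizes = c(8L, 4L)), "3 box sizes")
})

test_that("vessel density is the mask/ROI pixel fraction", {
  roi <- matrix(1L, 10, 10)
  expect_equal(vessel_density(roi, roi), 1)
  expect_equal(vessel_density(matrix(0L, 10, 10), roi), 0)
  half <- matrix(0L, 10, 10); half[, 1:5] <- 1L
  expect_equal(vessel_density(half, roi), 0.5)
  expect_error(vessel_density(half, matrix(0L, 10, 10)), "ROI")
})

test_that("velocity statistics use only non-zero pixels", {
  expect_equal(velocity_stats(matrix(c(0, 0, 3, 3), 2))$mean_velocity, 3)
  expect_equal(velocity_stats(matrix(c(0, 0, 3, 3), 2))$sd_velocity, 0)
  vs <- velocity_stats(matrix(c(2, 4), 1))
  expect_equal(vs$mean_velocity, 3)
  # adding zeros never changes the result
  vs2 <- velocity_stats(matrix(c(2, 4, 0, 0, 0, 0), 2))
  expect_equal(vs2$mean_velocity, vs$mean_velocity)
  expect_equal(vs2$sd_velocity, vs$sd_velocity)
  expect_true(is.na(velocity_stats(matrix(0, 2, 2))$mean_velocity))
})

test_that("cohort histograms average per-patient fractions equally", {
  one <- cohort_histograms(list(c(1, 1, 2)), bin_edges = c(0.5, 1.5, 2.5))
  expect_equal(one$distribution$fraction, c(2 / 3, 1 / 3))
  two <- cohort_histograms(list(rep(1, 10), rep(2, 3)),
                           bin_edges = c(0.5, 1.5, 2.5))
  expect_equal(two$distribution$fraction, c(0.5, 0.5))
  expect_equal(sum(two$distribution$fraction), 1, tolerance = 1e-9)
  skipped <- cohort_histograms(list(c(1, 2), numeric(0)),
                               bin_edges = c(0.5, 1.5, 2.5))
  expect_equal(skipped$n_patients_skipped, 1L)
})

test_that("sector assignment follows the counterclockwise half-open 30-degree rule", {
  fr <- sector_frame(hilum_mm = c(5, 5), axis = c(1, 0))
  # 15 degrees above the axis in physical coords = smaller image y
  p15 <- c(5 + cos(15 * pi / 180), 5 - sin(15 * pi / 180))
  expect_equal(sector_of(p15[1], p15[2], fr), 1L)
  p30 <- c(5 + cos(30 * pi / 180), 5 - sin(30 * pi / 180))
  expect_equal(sector_of(p30[1], p30[2], fr), 2L)
  # clockwise side (negative physical angle) falls in the last sector
  pm15 <- c(5 + cos(15 * pi / 180), 5 + sin(15 * pi / 180))
  expect_equal(sector_of(pm15[1], pm15[2], fr), 12L)
  # sector masks partition the ROI
  g <- sr_grid(20, 20, 0.5, 2L)
  total <- Reduce(`+`, lapply(1:12, function(k)
    ulmvasc:::sector_mask(fr, k, g)))
  expect_true(all(total == 1))
})

test_that("sector metrics restrict the five parameters to each wedge", {
  # two horizontal vessels left/right of the hilum at different speeds
  tr <- make_tracks(tibble::tibble(
    track_id = rep(1:2, each = 5),
    frame = rep(1:5, 2),
    x_mm = c(seq(5.2, 7.0, length.out = 5), seq(4.8, 3.0, length.out = 5)),
    y_mm = rep(c(4.99, 5.01), each = 5)))
  g <- sr_grid(100, 100, 0.1, 2L)
  maps <- sr_map_set(tr, g, 1)
  fr <- sector_frame(c(5, 5), axis = c(1, 0))
  sm <- sector_metrics(maps, tr, fr)
  expect_equal(nrow(sm), 12L)
  expect_equal(sum(sm$roi_px), prod(g$dim))
  expect_equal(sm$n_tracks[sm$sector == 1], 1L)   # right-going track
  # opposite wedge (sector 6 or 7) holds the other track
  expect_equal(sum(sm$n_tracks), 2L)
  expect_error(sector_metrics(maps, tr, sector_frame(c(50, 50))), "ROI")
})

test_that("quantify_testis bundles consistent scalars and histograms", {
  th <- seq(0, pi / 2, length.out = 60)
  tr <- make_tracks(tibble::tibble(track_id = 1L, frame = seq_along(th),
                                   x_mm = 2 + 1.5 * cos(th),
                                   y_mm = 2 + 1.5 * sin(th)))
  g <- sr_grid(40, 40, 0.1, 4L)
  maps <- sr_map_set(tr, g, 1)
  q <- quantify_testis(maps, tr)
  expect_s3_class(q, "quant_result")
  expect_gte(q$mean_tortuosity, 1)
  expect_true(q$vessel_density > 0 && q$vessel_density < 1)
  for (h in q$histograms)
    if (nrow(h)) expect_equal(sum(h$fraction), 1, tolerance = 1e-9)
  td <- tidy(q)
  expect_equal(nrow(td), 1L)
  expect_equal(td$mean_diameter, q$mean_diameter)
})
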