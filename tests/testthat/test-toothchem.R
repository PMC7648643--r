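make_scan <- function(values, blank, dwell = 0.25, speed = 40,
                      isotope = "138Ba", extra = list()) {
  intens <- data.frame(c(blank, values), check.names = FALSE)
  names(intens) <- isotope
  for (nm in names(extra)) intens[[nm]] <- extra[[nm]]
  line_scan("L1", intens, dwell, speed, n_blank_points = length(blank))
}

test_that("blank subtraction, LOD and zeroing follow the stated rules", {
  # blank with mean 100 and SD exactly 10 -> LOD 30
  blank <- c(90, 90, 100, 110, 110)
  expect_equal(sd(blank), 10)
  # blank-corrected 25 -> censored to 0; 35 -> kept as 35; negative -> 0
  scan <- make_scan(c(125, 135, 50, 100), blank)
  red <- reduce_scan(scan)
  expect_equal(red$blank_means[["138Ba"]], 100)
  expect_equal(red$lods[["138Ba"]], 30)
  expect_equal(red$corrected[["138Ba"]], c(0, 35, 0, 0))
  # no corrected value may lie strictly between 0 and the LOD
  expect_false(any(red$corrected[["138Ba"]] > 0 &
                     red$corrected[["138Ba"]] < red$lods[["138Ba"]]))

  # signal identically equal to the blank mean -> all zero
  scan <- make_scan(rep(100, 6), blank)
  expect_true(all(reduce_scan(scan)$corrected[["138Ba"]] == 0))

  # blank window must be shorter than the scan and hold >= 2 points
  expect_error(line_scan("L", data.frame(`138Ba` = 1:5, check.names = FALSE),
                         0.25, 40, n_blank_points = 5), "shorter")
  expect_error(reduce_scan(make_scan(c(1, 2), blank = 100)), "at least 2")
})

test_that("reduction is idempotent on a blank-zero scan", {
  vals <- c(0, 40, 80, 120)
  scan <- make_scan(vals, blank = c(0, 0, 0))
  red <- reduce_scan(scan)
  expect_equal(red$corrected[["138Ba"]], vals)
  scan2 <- make_scan(red$corrected[["138Ba"]], blank = c(0, 0, 0))
  expect_equal(reduce_scan(scan2)$corrected, red$corrected)
})

test_that("one-point Ba calibration is exact and linear", {
  # sample ratio equal to the reference ratio -> the in-house 281 ug/g
  expect_identical(calibrate_ba(0.05, 0.05), 281)
  expect_identical(calibrate_ba(0.025, 0.05), 140.5)
  # linearity: scaling the sample ratio scales the output
  expect_equal(calibrate_ba(3 * 0.01, 0.05), 3 * calibrate_ba(0.01, 0.05))
  expect_error(calibrate_ba(0.05, 0), "positive")
  expect_error(calibrate_ba(0.05, -1), "positive")
})

test_that("georeferencing spaces points evenly and propagates undefined", {
  blank <- rep(0, 3)
  ba <- c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100)
  ca <- c(100, 100, 0, 100, 100, 100, 100, 100, 100, 100)
  scan <- line_scan("L1", data.frame(`138Ba` = c(blank, ba),
                                     `43Ca` = c(blank, ca),
                                     check.names = FALSE),
                    0.25, 40, start_xy = c(0, 0), end_xy = c(90, 0),
                    n_blank_points = 3)
  g <- georeference_scan(reduce_scan(scan), ratios = "138Ba/43Ca")
  expect_equal(g$x_um, seq(0, 90, by = 10))
  expect_equal(g$y_um, rep(0, 10))
  # censored denominator -> undefined ratio at that point
  expect_true(is.na(g[["138Ba/43Ca"]][3]))
  expect_equal(g[["138Ba/43Ca"]][1], 0.1)

  # n = 1: single point at start
  s1 <- line_scan("L2", data.frame(`138Ba` = c(0, 0, 5), check.names = FALSE),
                  0.25, 40, start_xy = c(3, 4), end_xy = c(3, 4),
                  n_blank_points = 2)
  g1 <- georeference_scan(reduce_scan(s1), ratios = character(0))
  expect_equal(c(g1$x_um, g1$y_um), c(3, 4))

  # degenerate geometry with n > 1
  s2 <- line_scan("L3", data.frame(`138Ba` = c(0, 0, 5, 6), check.names = FALSE),
                  0.25, 40, start_xy = c(0, 0), end_xy = c(0, 0),
                  n_blank_points = 2)
  expect_error(georeference_scan(reduce_scan(s2)), "degenerate geometry")
  expect_error(georeference_scan(reduce_scan(s1), ratios = "1X/2Y"),
               "not present")
})

test_that("ROI statistics match the sorting/interpolation oracle", {
  pts <- data.frame(x_um = c(1:5, 50), y_um = 0, point = 1:6,
                    v = c(1, 2, 3, 4, 5, 99), check.names = FALSE)
  roi <- roi_polygon("box", c(0, 6, 6, 0), c(-1, -1, 1, 1))
  st <- roi_statistics(pts, list(roi), ratio_label = "v")
  expect_identical(st$n_points, 5L)
  expect_identical(st$median, 3)
  expect_identical(st$p25, 2)
  expect_identical(st$p75, 4)
  expect_identical(st$p5, unname(quantile(1:5, 0.05)))
  expect_identical(st$mean, 3)
  expect_identical(st$sd, sd(1:5))
  # ordering invariant
  expect_true(st$p5 <= st$p25 && st$p25 <= st$median &&
                st$median <= st$p75 && st$p75 <= st$p95)

  # constant values: mean = median = v, sd = 0
  pts2 <- data.frame(x_um = 1:4, y_um = 0, v = 7)
  st2 <- roi_statistics(pts2, list(roi), "v")
  expect_identical(c(st2$mean, st2$median, st2$sd), c(7, 7, 0))

  # boundary counts as inside; outside counts nowhere; NA excluded
  pts3 <- data.frame(x_um = c(0, 6, 7, 3), y_um = c(-1, 1, 0, 0),
                     v = c(1, 2, 3, NA))
  st3 <- roi_statistics(pts3, list(roi), "v")
  expect_identical(st3$n_points, 2L)  # the two boundary points only

  # empty ROI: warned, n 0, NA stats
  far <- roi_polygon("far", c(100, 101, 101, 100), c(0, 0, 1, 1))
  expect_warning(st4 <- roi_statistics(pts, list(far), "v"), "no points")
  expect_identical(st4$n_points, 0L)
  expect_true(is.na(st4$mean))

  # overlapping ROIs both capture shared points
  half <- roi_polygon("half", c(0, 3.5, 3.5, 0), c(-1, -1, 1, 1))
  st5 <- roi_statistics(pts, list(roi, half), "v")
  expect_identical(st5$n_points, c(5L, 3L))
})

test_that("ROI polygons are validated", {
  expect_error(roi_polygon("p", c(0, 1), c(0, 1)), "at least 3")
  # explicit closing vertex is tolerated
  p <- roi_polygon("p", c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  expect_length(p$x, 4)
  # bow-tie self-intersection rejected
  expect_error(roi_polygon("bow", c(0, 1, 1, 0), c(0, 1, 0, 1)),
               "self-intersecting")
})

test_that("layer thickness counts the surface-adjacent supra run", {
  # prenatal mean 0.20, sd 0.01 -> threshold 0.23; 5 supra points at
  # 0.25 s x 40 um/s -> 50 um
  ratios <- c(0.2, 0.21, 0.2, 0.3, 0.31, 0.29, 0.30, 0.32)
  th <- layer_thickness(ratios, 0.20, 0.01, 0.25, 40)
  expect_equal(th$threshold, 0.23)
  expect_identical(th$n_supra_points, 5L)
  expect_equal(th$thickness_um, 50)
  expect_equal(th$uncertainty_um, 20)

  # no supra points -> thickness 0
  th0 <- layer_thickness(c(0.1, 0.15), 0.2, 0.01, 0.25, 40)
  expect_identical(th0$thickness_um, 0)

  # interior isolated spike does not count; undefined breaks the run
  th1 <- layer_thickness(c(0.9, 0.1, 0.3, 0.3), 0.2, 0.01, 0.25, 40)
  expect_identical(th1$n_supra_points, 2L)
  th2 <- layer_thickness(c(0.3, 0.3, NA, 0.3), 0.2, 0.01, 0.25, 40)
  expect_identical(th2$n_supra_points, 1L)

  expect_error(layer_thickness(numeric(0), 0.2, 0.01, 0.25, 40), "empty")
})

test_that("crown formation time composes consistently", {
  # zero segments: intercept only
  expect_equal(crown_formation_time(numeric(0), 0.5, 10)$total_days, 10)
  # slope 0.5 day/um, cumulative 300 um -> 150 days
  ct <- crown_formation_time(c(100, 200), 0.5, 0)
  expect_equal(ct$total_days, 150)
  expect_equal(ct$per_segment_days, c(50, 100))
  # concatenation invariance under the cumulative rule
  ct2 <- crown_formation_time(300, 0.5, 0)
  expect_equal(ct2$total_days, ct$total_days)
  ct3 <- crown_formation_time(c(50, 50, 200), 0.5, 7)
  expect_equal(ct3$total_days, crown_formation_time(300, 0.5, 7)$total_days)
  # per-segment rule adds the intercept per segment
  ct4 <- crown_formation_time(c(100, 200), 0.5, 10, rule = "per_segment")
  expect_equal(ct4$total_days, 170)
  # coefficients are mandatory
  expect_error(crown_formation_time(c(100), NULL, NULL), "configuration")
  expect_error(crown_formation_time(c(-5), 0.5, 0), "positive")
})

test_that("collagen C:N quality control", {
  qc <- collagen_qc(42, 15)
  expect_equal(qc$atomic_cn_ratio, (42 / 12.011) / (15 / 14.007))
  expect_equal(qc$atomic_cn_ratio, 3.2653, tolerance = 1e-4)
  expect_true(qc$pass)
  qc2 <- collagen_qc(40, 10)
  expect_equal(qc2$atomic_cn_ratio, 4.6647, tolerance = 1e-4)
  expect_false(qc2$pass)
  expect_error(collagen_qc(40, 0), "positive")
})

test_that("phantom scans honour the stated world", {
  # noiseless phantom: reduced ratios exactly the band levels
  sc <- synth_scan(noise_sd = 0, seed = 1)
  red <- reduce_scan(sc)
  g <- georeference_scan(red, ratios = "138Ba/43Ca")
  expect_equal(g[["138Ba/43Ca"]], attr(sc, "true_ratio"), tolerance = 1e-12)

  # determinism under the seed
  s1 <- synth_scan(noise_sd = 0.05, seed = 9)
  s2 <- synth_scan(noise_sd = 0.05, seed = 9)
  expect_identical(s1$intensities, s2$intensities)

  # a >=30% pre->post step is recovered and ordered by ROI statistics
  sc <- synth_scan(phantom_bands(pre_ratio = 0.4, post_ratio = 0.52),
                   noise_sd = 0.05, seed = 33)
  bands <- attr(sc, "bands")
  g <- georeference_scan(reduce_scan(sc), ratios = "138Ba/43Ca")
  spacing <- 10
  rois <- lapply(seq_len(nrow(bands)), function(i) {
    roi_polygon(bands$label[i],
                c((bands$from[i] - 1) * spacing - 1,
                  (bands$to[i] - 1) * spacing + 1,
                  (bands$to[i] - 1) * spacing + 1,
                  (bands$from[i] - 1) * spacing - 1),
                c(-1, -1, 1, 1))
  })
  st <- roi_statistics(g, rois, "138Ba/43Ca")
  expect_identical(st$n_points, c(15L, 20L, 10L))
  for (i in 1:3) {
    se <- st$sd[i] / sqrt(st$n_points[i])
    expect_lt(abs(st$mean[i] - bands$ratio[i]), 3 * se + 1e-9)
  }
  expect_gt(st$mean[3], st$mean[2])

  expect_error(synth_scan(phantom_bands(pre_um = -5)), "positive")
})

test_that("surface-contamination screen flags an Al/Ca gradient", {
  sc <- synth_scan(noise_sd = 0.02, seed = 4,
                   surface_contamination = list(depth_um = 20,
                                                al_ca_ratio = 0.5))
  g <- georeference_scan(reduce_scan(sc), ratios = c("138Ba/43Ca",
                                                     "27Al/43Ca"))
  res <- screen_surface_contamination(g, point_spacing_um = 10)
  expect_true(res$flag)

  sc0 <- synth_scan(noise_sd = 0.02, seed = 4)
  g0 <- georeference_scan(reduce_scan(sc0), ratios = c("138Ba/43Ca",
                                                       "27Al/43Ca"))
  res0 <- screen_surface_contamination(g0, point_spacing_um = 10)
  expect_false(res0$flag)
})
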