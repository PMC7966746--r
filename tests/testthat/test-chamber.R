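test_that("mask volumetry counts voxels and scales with spacing", {
  m <- roi_mask(array(TRUE, dim = c(10, 10, 10, 2)), "LA", c(1, 1, 1))
  vc <- volume_from_mask(m, c(0, 100))
  expect_equal(vc$volumes_ml, c(1, 1))  # 1000 voxels of 1 mm^3

  # slice summation with increment = z spacing equals voxel volumetry
  vc_s <- volume_from_mask(m, c(0, 100), method = "slice",
                           slice_increment_mm = 1)
  expect_equal(vc_s$volumes_ml, vc$volumes_ml)
  # thickness + gap increment doubles the volume of a gapped stack
  vc_g <- volume_from_mask(m, c(0, 100), method = "slice",
                           slice_increment_mm = 2)
  expect_equal(vc_g$volumes_ml, 2 * vc$volumes_ml)

  # shrinking each linear spacing by 2^(-1/3) halves the volume exactly
  m2 <- roi_mask(m$m, "LA", rep(2^(-1 / 3), 3))
  expect_equal(volume_from_mask(m2, c(0, 100))$volumes_ml,
               vc$volumes_ml / 2)
})

test_that("landmarks and the Table-1 decomposition reproduce printed values", {
  # control group means (indexed mL/m^2)
  cf <- chamber_function(list(v_max_ml = 36.6, v_preac_ml = 26.8,
                              v_min_ml = 15.8))
  expect_equal(cf$reservoir_ml, 20.8)
  expect_equal(cf$conduit_ml, 9.8)
  expect_equal(cf$active_ml, 11.0)
  expect_equal(cf$total_pct, 20.8 * 100 / 36.6)
  expect_equal(cf$passive_pct, 9.8 * 100 / 36.6)
  expect_equal(cf$booster_pct, 11.0 * 100 / 26.8)
  # AF group active emptying
  cf_af <- chamber_function(list(v_max_ml = 39.6, v_preac_ml = 29.5,
                                 v_min_ml = 19.9))
  expect_equal(cf_af$active_ml, 9.6)

  # degenerate motionless atrium
  cf0 <- chamber_function(list(v_max_ml = 50, v_preac_ml = 50, v_min_ml = 50))
  expect_equal(cf0$reservoir_ml, 0)
  expect_equal(cf0$total_pct, 0)

  expect_error(chamber_function(list(v_max_ml = 30, v_preac_ml = 40,
                                     v_min_ml = 20)),
               class = "la_landmark_error")
})

test_that("reservoir = conduit + active and total = 100 reservoir / max, always", {
  set.seed(20)
  for (i in 1:50) {
    v <- sort(runif(3, 5, 120), decreasing = TRUE)
    cf <- chamber_function(list(v_max_ml = v[1], v_preac_ml = v[2],
                                v_min_ml = v[3]))
    expect_equal(cf$reservoir_ml, cf$conduit_ml + cf$active_ml)
    expect_equal(cf$total_pct, 100 * cf$reservoir_ml / v[1])
  }
})

test_that("phantom volume curve recovers the generative landmarks", {
  ds <- make_phantom(tiny_spec(seed = 14))
  vc <- volume_from_mask(ds$mask_la, ds$field$times_ms)
  lm <- find_landmarks(vc, ds$timings)
  truth <- ds$truth$true_landmarks_ml
  expect_lt(abs(lm$v_max_ml - truth[["v_max"]]) / truth[["v_max"]], 0.05)
  expect_lt(abs(lm$v_preac_ml - truth[["v_preac"]]) / truth[["v_preac"]], 0.05)
  expect_lt(abs(lm$v_min_ml - truth[["v_min"]]) / truth[["v_min"]], 0.05)
  expect_equal(lm$i_min, 1)  # the cycle starts at minimum volume
})

test_that("biplane area-length volume reduces to the sphere closed form", {
  r <- 30
  v <- lv_biplane_area_length(pi * r^2, pi * r^2, 2 * r)
  expect_equal(v, 4 / 3 * pi * r^3 / 1000, tolerance = 1e-12)  # 113.1 mL
  expect_equal(ejection_fraction(173.4, 61.8), (173.4 - 61.8) * 100 / 173.4)
  expect_equal(lv_mass(150, 150), 0)
  expect_equal(lv_mass(150, 100), 52.5)
  expect_error(lv_mass(90, 100), class = "la_parameter_error")
  expect_error(ejection_fraction(50, 60), class = "la_parameter_error")
  expect_error(lv_biplane_area_length(-1, 10, 10), class = "la_parameter_error")
})

make_semicircle_contours <- function(radii_by_frame, times_ms) {
  theta <- pi * (0:39) / 39
  rows <- list()
  for (view in c("2ch", "4ch")) {
    for (f in seq_along(radii_by_frame)) {
      r <- radii_by_frame[f]
      rows[[length(rows) + 1]] <- data.frame(
        frame = f, view = view, point_index = 1:40,
        x_mm = r * cos(theta), y_mm = r * sin(theta))
    }
  }
  contour_sequence(do.call(rbind, rows), times_ms = times_ms)
}

test_that("strain is the relative arc-length change from the reference frame", {
  ct <- make_semicircle_contours(c(10, 10, 10), c(0, 100, 200))
  g <- gls_curve(ct)
  expect_equal(g$gls_pct, rep(0, 3))
  expect_equal(g$strain_rate_per_s, rep(0, 3))

  # 20% longer arc at the second frame
  ct2 <- make_semicircle_contours(c(10, 12, 10), c(0, 100, 200))
  g2 <- gls_curve(ct2)
  expect_equal(g2$gls_pct[2], 20, tolerance = 1e-10)

  # point-count mismatch across frames is a tracking error
  bad <- ct$points[!(ct$points$frame == 2 & ct$points$point_index == 40), ]
  expect_error(contour_sequence(bad, times_ms = c(0, 100, 200)),
               class = "la_tracking_error")
})

test_that("strain rate matches the analytic derivative of a sinusoidal length", {
  n <- 40
  rr <- 1000
  times <- (0:(n - 1)) * rr / n
  radii <- 10 * (1 + 0.1 * sin(2 * pi * times / rr))
  g <- gls_curve(make_semicircle_contours(radii, times))
  # strain = 10 sin(w t) %, rate = 0.1 w cos(w t) per second
  w <- 2 * pi / (rr / 1000)
  analytic <- 0.1 * w * cos(2 * pi * times / rr)
  interior <- 2:(n - 1)
  expect_lt(max(abs(g$strain_rate_per_s[interior] - analytic[interior])), 0.02)
})

test_that("strain phases split reservoir into conduit and active parts", {
  # triangular rise to 20%, plateau at 6.8% at pre-ac, fall to 0
  rr <- 1000
  tm <- random_timings(rr)
  times <- seq(0, 900, by = 30)  # sampling grid contains 390 and 720
  s <- approx(c(0, 390, 720, 930), c(0, 20, 6.8, 0), xout = times,
              rule = 2)$y
  radii <- 10 * (1 + s / 100)
  g <- gls_curve(make_semicircle_contours(radii, times))
  ph <- strain_phases(g, tm)
  expect_equal(ph$reservoir_strain, 20, tolerance = 1e-6)
  expect_equal(ph$active_strain, 6.8, tolerance = 1e-6)
  expect_equal(ph$conduit_strain, 13.2, tolerance = 1e-6)
  expect_gt(ph$peak_positive, 0)
  expect_gt(ph$peak_early_negative, 0)
  expect_gt(ph$peak_late_negative, 0)

  # monotone non-decreasing strain has no negative-rate peaks
  s_mono <- seq(0, 20, length.out = length(times))
  g_mono <- gls_curve(make_semicircle_contours(10 * (1 + s_mono / 100), times))
  expect_error(strain_phases(g_mono, tm), class = "la_timing_error")
})

test_that("phantom contours recover the prescribed strain phases within 1%", {
  ds <- make_phantom(tiny_spec(seed = 15))
  ph <- strain_phases(gls_curve(ds$contours), ds$timings)
  truth <- ds$truth$true_strain
  expect_lt(abs(ph$reservoir_strain - truth$reservoir) / truth$reservoir, 0.01)
  expect_lt(abs(ph$active_strain - truth$active) / truth$active, 0.01)
  expect_lt(abs(ph$conduit_strain - truth$conduit) / truth$conduit, 0.01)
})
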