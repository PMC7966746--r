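test_that("speed is the 3-directional magnitude", {
  fld <- uniform_field(c(3, 4, 0))
  expect_true(all(speed_field(fld) == 5))
  expect_true(all(speed_field(uniform_field(c(0, 0, 0))) == 0))
})

test_that("velocity-time curve averages in-mask speeds per frame", {
  fld <- uniform_field(c(12, 0, 0))
  vc <- velocity_time_curve(fld, full_mask(fld))
  expect_equal(vc$spatial_mean_cmps, rep(12, 4))

  # two voxels with speeds 10 and 20 average to 15
  v <- array(0, dim = c(2, 1, 1, 3, 1))
  v[1, 1, 1, 1, 1] <- 10
  v[2, 1, 1, 1, 1] <- 20
  f2 <- velocity_field(v, c(3, 3, 3), 0, 800)
  vc2 <- velocity_time_curve(f2, full_mask(f2))
  expect_equal(vc2$spatial_mean_cmps, 15)

  # empty mask frame is an error
  m <- full_mask(fld)
  m$m[, , , 2] <- FALSE
  expect_error(velocity_time_curve(fld, m), class = "la_region_error")
})

test_that("windowed stats take the time-mean and temporal peak of the curve", {
  tm <- random_timings(rr = 1000)
  flat <- structure(list(times_ms = c(0, 300, 600), region = "LA",
                         spatial_mean_cmps = c(12, 12, 12), n_voxels = rep(8L, 3)),
                    class = "velocity_time_curve")
  for (w in c("RR", "systole", "diastole", "E", "A")) {
    expect_equal(unname(window_velocity_stats(flat, tm, w)), c(12, 12))
  }
  ramp <- flat
  ramp$spatial_mean_cmps <- c(10, 20, 30)
  expect_equal(unname(window_velocity_stats(ramp, tm, "RR")), c(20, 30))
  # a window with no frame raises a timing error
  late <- flat
  late$times_ms <- c(500, 600, 700)
  expect_error(window_velocity_stats(late, tm, "systole"),
               class = "la_timing_error")
})

test_that("stasis counts samples below threshold in both modes", {
  all_still <- uniform_field(c(0, 0, 0))
  m <- full_mask(all_still)
  expect_equal(stasis_fraction(all_still, m, mode = "timefrac"), 100)
  expect_equal(stasis_fraction(all_still, m, mode = "strict"), 100)
  fast <- uniform_field(c(20, 0, 0))
  expect_equal(stasis_fraction(fast, full_mask(fast)), 0)
  expect_equal(stasis_fraction(fast, full_mask(fast), mode = "strict"), 0)

  # exactly half of the voxel-frame samples below threshold
  v <- array(0, dim = c(2, 1, 1, 3, 2))
  v[1, 1, 1, 1, ] <- 5    # always slow
  v[2, 1, 1, 1, ] <- 15   # always fast
  f <- velocity_field(v, c(3, 3, 3), c(0, 100), 800)
  expect_equal(stasis_fraction(f, full_mask(f), mode = "timefrac"), 50)
  expect_equal(stasis_fraction(f, full_mask(f), mode = "strict"), 50)

  # a voxel intermittently slow counts in timefrac but not in strict
  v[2, 1, 1, 1, 1] <- 5
  f2 <- velocity_field(v, c(3, 3, 3), c(0, 100), 800)
  expect_equal(stasis_fraction(f2, full_mask(f2), mode = "timefrac"), 75)
  expect_equal(stasis_fraction(f2, full_mask(f2), mode = "strict"), 50)
})

test_that("kinetic energy follows the voxel-mass unit contract", {
  # one voxel of 0.0288 mL moving at 20 cm/s:
  # 0.5 * 1.025 g/mL * 0.0288 mL * 400 cm^2/s^2 * 1e-4 = 5.904e-4 mJ
  v <- array(0, dim = c(1, 1, 1, 3, 1))
  v[1, 1, 1, 1, 1] <- 20
  f <- velocity_field(v, c(3.0, 3.0, 3.2), 0, 800)
  ke <- kinetic_energy_curve(f, full_mask(f))
  expect_equal(ke$ke_mj, 5.904e-4, tolerance = 1e-12)

  expect_equal(kinetic_energy_curve(uniform_field(c(0, 0, 0)),
                                    full_mask(uniform_field(c(0, 0, 0))))$ke_mj,
               rep(0, 4))

  # doubling all velocities quadruples KE exactly
  f2 <- velocity_field(2 * v, c(3.0, 3.0, 3.2), 0, 800)
  expect_equal(kinetic_energy_curve(f2, full_mask(f2))$ke_mj, 4 * ke$ke_mj)
})

test_that("KE indexing converts mJ to uJ/mL by the maximum LA volume", {
  expect_equal(index_ke(1, 50), 20)
  expect_equal(index_ke(0, 59.4), 0)
  expect_equal(index_ke(0.95, 59.4), 950 / 59.4)
  expect_error(index_ke(1, 0), class = "la_parameter_error")
})

test_that("pipeline metrics match the brute-force oracle on random fields", {
  for (seed in 1:5) {
    fld <- random_field(seed)
    masks <- random_masks(seed)
    tm <- random_timings()
    om <- oracle_metrics(fld, masks, tm, v_max_ml = 40)
    pm <- flow_metrics(fld, masks, tm, v_max_ml = 40)
    expect_lt(max_metric_rel_err(pm$LA, om$LA), 1e-10)
    expect_lt(max_metric_rel_err(pm$LAA, om$LAA), 1e-10)
  }
})

test_that("velocity scaling acts monotonically on stasis and quadratically on KE", {
  for (seed in 6:10) {
    fld <- random_field(seed, vel_sd = 8)
    m <- random_masks(seed)$LA
    s <- 1.7
    scaled <- velocity_field(s * fld$v, fld$spacing_mm, fld$times_ms, fld$rr_ms)
    expect_lte(stasis_fraction(scaled, m), stasis_fraction(fld, m))
    expect_equal(kinetic_energy_curve(scaled, m)$ke_mj,
                 s^2 * kinetic_energy_curve(fld, m)$ke_mj, tolerance = 1e-12)
  }
})

test_that("LAA-vs-LA contrasts behave as paired deltas", {
  ds <- make_phantom(tiny_spec(seed = 13, laa_scale = 0.5))
  fm <- flow_metrics(ds$field, list(LA = ds$mask_la, LAA = ds$mask_laa),
                     ds$timings, v_max_ml = 15)
  d <- compare_la_vs_laa(fm)
  expect_equal(nrow(d), 1)
  expect_lt(d$d_velocity_mean_rr, 0)
  expect_lt(d$d_velocity_peak_rr, 0)
  expect_gt(d$d_stasis_pct, 0)
  # identical regions give zero deltas
  same <- list(LA = fm$LA, LAA = fm$LA)
  same$LAA$region <- "LAA"
  d0 <- compare_la_vs_laa(same)
  expect_equal(unlist(d0), c(d_velocity_mean_rr = 0, d_velocity_peak_rr = 0,
                             d_stasis_pct = 0))
  expect_error(compare_la_vs_laa(list(list(LA = fm$LA))),
               class = "la_region_error")
})

test_that("mean velocity and stasis are strongly inversely coupled across subjects", {
  # small synthetic cohort; the coupling is a property of the stasis
  # definition, echoing the strong inverse relation seen in vivo
  coh <- make_cohort(n_af = 7, n_ctrl = 7, seed = 99)
  vel <- numeric(0); st <- numeric(0)
  for (s in coh) {
    m <- region_flow_metrics(s$data$field, s$data$mask_la, s$data$timings,
                             s$spec$volume_params$v_max_ml)
    vel <- c(vel, m$velocity_mean_rr)
    st <- c(st, m$stasis_pct)
  }
  expect_lt(spearman_cor(vel, st)$rho, -0.8)
})
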