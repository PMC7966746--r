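# Shared fixtures: small fast phantom specs and random fields, built in code.

tiny_spec <- function(seed = 1L, noise_sd_cmps = 0,
                      offset_plane = matrix(0, 3, 4),
                      heterogeneity = 0.55, constant_cmps = NULL,
                      laa_scale = 0.685, n_frames = 10L) {
  phantom_spec(
    grid_dims = c(18L, 18L, 18L),
    voxel_spacing_mm = c(3.1, 3.1, 3.0),
    n_frames = n_frames,
    rr_ms = 900,
    rr_coverage = 0.9,
    volume_params = list(v_max_ml = 15, v_preac_ml = 11, v_min_ml = 7,
                         t_min_frac = 0.93, t_preac_frac = 0.72),
    velocity_params = list(systolic_cmps = 18.4, e_peak_cmps = 28.4,
                           a_peak_cmps = 10, baseline_cmps = 12.5,
                           spatial_heterogeneity = heterogeneity,
                           constant_cmps = constant_cmps),
    appendage_params = list(velocity_scale = laa_scale, radius_mm = 5,
                            centre_offset_mm = NULL),
    strain_params = list(reservoir_pct = 20.8, active_pct = 6.8),
    noise_sd_cmps = noise_sd_cmps,
    offset_plane = offset_plane,
    seed = seed
  )
}

# Random small velocity field + masks + timings for oracle-equivalence and
# property tests.
random_field <- function(seed, dims = c(6L, 6L, 6L), nt = 8L, vel_sd = 12) {
  set.seed(seed)
  rr <- 800
  v <- array(rnorm(prod(dims) * 3 * nt, sd = vel_sd), dim = c(dims, 3, nt))
  times <- (seq_len(nt) - 1) * 0.9 * rr / nt
  velocity_field(v, c(2.5, 2.5, 3), times, rr)
}

random_masks <- function(seed, dims = c(6L, 6L, 6L), nt = 8L) {
  set.seed(seed + 1000)
  mk <- function(region) {
    m <- array(runif(prod(dims) * nt) < 0.4, dim = c(dims, nt))
    for (t in seq_len(nt)) {
      if (!any(m[, , , t])) m[1, 1, 1, t] <- TRUE  # keep frames non-empty
    }
    roi_mask(m, region, c(2.5, 2.5, 3))
  }
  list(LA = mk("LA"), LAA = mk("LAA"))
}

random_timings <- function(rr = 800) {
  cardiac_timings(systole_ms = c(0, 0.4 * rr),
                  diastole_ms = c(0.4 * rr, 0.9 * rr),
                  t_e_peak_ms = 0.52 * rr, t_a_peak_ms = 0.82 * rr,
                  t_preac_ms = 0.72 * rr, rr_ms = rr)
}

# Uniform homogeneous field: every voxel velocity (vx, vy, vz) at all frames.
uniform_field <- function(vec, dims = c(4L, 4L, 4L), nt = 4L,
                          spacing = c(3, 3, 3), rr = 1000) {
  v <- array(0, dim = c(dims, 3, nt))
  for (cc in 1:3) v[, , , cc, ] <- vec[cc]
  velocity_field(v, spacing, (seq_len(nt) - 1) * 0.9 * rr / nt, rr)
}

full_mask <- function(field, region = "LA") {
  d <- dim(field$v)
  roi_mask(array(TRUE, dim = d[c(1:3, 5)]), region, field$spacing_mm)
}

# Relative error helper used by equivalence tests
rel_err <- function(a, b) {
  denom <- pmax(abs(a), abs(b), 1e-30)
  abs(a - b) / denom
}

# Compare shared numeric metric entries between two metric lists
max_metric_rel_err <- function(m1, m2) {
  keys <- intersect(names(m1), names(m2))
  keys <- keys[vapply(keys, function(k) is.numeric(m1[[k]]), logical(1))]
  max(vapply(keys, function(k) rel_err(m1[[k]], m2[[k]]), numeric(1)))
}
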