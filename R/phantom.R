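# Synthetic dynamic-atrium 4D-flow phantom with analytic ground truth.
#
# The left atrium is a time-varying ellipsoid (semi-axes a, a, 1.3a) whose
# voxelized volume tracks an analytic volume curve; the appendage is a small
# attached spherical lobe excluded from the LA mask. Per-voxel speed follows
# a temporal envelope (systolic hump, E peak, A peak) scaled by a static
# lognormal spatial heterogeneity field; directions come from a smooth
# template under a random rotation (all reported metrics depend on the
# magnitude only). Gaussian noise and a linear per-component offset plane
# emulate measurement noise and residual eddy-current offsets.

# Fixed phase landmarks of the cycle (fractions of the R-R interval).
PH_T_MAX_FRAC <- 0.40   # end of ventricular systole = LA volume maximum
PH_E_PEAK_FRAC <- 0.52
PH_ELONG <- 1.3         # long-axis elongation of the LA ellipsoid
# Raised-cosine bump widths of the speed envelope (phase units)
PH_W_SYS <- 0.22
PH_W_E <- 0.11
PH_W_A <- 0.09

#' Specify a synthetic dynamic-atrium dataset
#'
#' Collects every generative parameter of the phantom. Defaults give a
#' mid-sized atrium on the acquisition grid geometry typical for 4D-flow
#' CMR (3.1 x 3.1 x 3 mm voxels, 20 frames over 90% of the R-R interval).
#'
#' @param grid_dims integer length-3, voxels per axis.
#' @param voxel_spacing_mm positive length-3, mm.
#' @param n_frames number of flow frames (>= 8).
#' @param rr_ms R-R interval, ms.
#' @param rr_coverage fraction of the R-R interval covered by flow frames
#'   (prospective gating truncates the late cycle).
#' @param volume_params list: `v_max_ml`, `v_preac_ml`, `v_min_ml`
#'   (`v_max >= v_preac >= v_min > 0`), and phase fractions `t_min_frac`,
#'   `t_preac_frac` in (0, 1).
#' @param velocity_params list: `systolic_cmps`, `e_peak_cmps`,
#'   `a_peak_cmps` (bump amplitudes of the spatial-mean speed envelope,
#'   cm/s), `baseline_cmps` (diastasis floor), `spatial_heterogeneity`
#'   (coefficient of variation of per-voxel speed), and optionally
#'   `constant_cmps` to force a flat envelope.
#' @param appendage_params list: `velocity_scale` in (0, 1], `radius_mm`,
#'   and optionally `centre_offset_mm` (offset of the lobe centre from the
#'   LA centre; default places the lobe on the +x flank).
#' @param strain_params list: `reservoir_pct`, `active_pct` prescribing the
#'   global longitudinal strain curve encoded in the generated contours.
#' @param noise_sd_cmps per-component Gaussian noise sd, cm/s.
#' @param offset_plane 3x4 matrix; row c gives (a, b, c, d) of the linear
#'   offset a + b x + c y + d z (cm/s, world mm) added to component c.
#' @param seed integer RNG seed; identical spec + seed reproduce the
#'   dataset bit-exactly.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dims = c(30L, 30L, 30L),
                         voxel_spacing_mm = c(3.1, 3.1, 3.0),
                         n_frames = 20L,
                         rr_ms = 1000,
                         rr_coverage = 0.9,
                         volume_params = list(
                           v_max_ml = 70, v_preac_ml = 51, v_min_ml = 30,
                           t_min_frac = 0.93, t_preac_frac = 0.72),
                         velocity_params = list(
                           systolic_cmps = 18.4, e_peak_cmps = 28.4,
                           a_peak_cmps = 10.0, baseline_cmps = 12.5,
                           spatial_heterogeneity = 0.55,
                           constant_cmps = NULL),
                         appendage_params = list(
                           velocity_scale = 0.685, radius_mm = 8.5,
                           centre_offset_mm = NULL),
                         strain_params = list(
                           reservoir_pct = 20.8, active_pct = 6.8),
                         noise_sd_cmps = 0,
                         offset_plane = matrix(0, 3, 4),
                         seed = 1L) {
  if (n_frames < 8) stop_la("la_parameter_error", "n_frames must be >= 8")
  check_positive(voxel_spacing_mm, "voxel_spacing_mm")
  check_positive(rr_ms, "rr_ms")
  if (rr_coverage <= 0 || rr_coverage > 1) {
    stop_la("la_parameter_error", "rr_coverage must be in (0, 1]")
  }
  vp <- volume_params
  if (!(vp$v_max_ml >= vp$v_preac_ml && vp$v_preac_ml >= vp$v_min_ml &&
        vp$v_min_ml > 0)) {
    stop_la("la_parameter_error",
            "volume landmarks must satisfy v_max >= v_preac >= v_min > 0")
  }
  if (vp$t_preac_frac <= 0 || vp$t_min_frac >= 1 ||
      vp$t_preac_frac >= vp$t_min_frac || vp$t_preac_frac <= PH_T_MAX_FRAC) {
    stop_la("la_parameter_error",
            "phase fractions must satisfy t_max < t_preac < t_min < 1")
  }
  if (velocity_params$spatial_heterogeneity < 0) {
    stop_la("la_parameter_error", "spatial_heterogeneity must be >= 0")
  }
  if (appendage_params$velocity_scale <= 0 || appendage_params$velocity_scale > 1) {
    stop_la("la_parameter_error", "appendage velocity_scale must be in (0, 1]")
  }
  if (noise_sd_cmps < 0) stop_la("la_parameter_error", "noise_sd_cmps must be >= 0")
  if (!is.matrix(offset_plane) || !all(dim(offset_plane) == c(3, 4))) {
    stop_la("la_parameter_error", "offset_plane must be a 3x4 matrix")
  }
  structure(list(grid_dims = as.integer(grid_dims),
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 n_frames = as.integer(n_frames), rr_ms = rr_ms,
                 rr_coverage = rr_coverage, volume_params = vp,
                 velocity_params = velocity_params,
                 appendage_params = appendage_params,
                 strain_params = strain_params,
                 noise_sd_cmps = noise_sd_cmps,
                 offset_plane = offset_plane, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Smooth C1 interpolation between keyframes: half-cosine segments with zero
# slope at every landmark.
cosine_track <- function(phase, key_p, key_v) {
  phase <- phase %% 1
  out <- numeric(length(phase))
  for (s in seq_len(length(key_p) - 1)) {
    inseg <- phase >= key_p[s] & phase <= key_p[s + 1]
    if (!any(inseg)) next
    u <- (phase[inseg] - key_p[s]) / (key_p[s + 1] - key_p[s])
    out[inseg] <- key_v[s] + (key_v[s + 1] - key_v[s]) * (1 - cos(pi * u)) / 2
  }
  out
}

# Analytic LA volume (mL) at cycle phase in [0, 1): minimum at the R-wave,
# filling to v_max at end-systole, passive emptying to the pre-ac plateau,
# active emptying to v_min, then constant until the next R-wave.
la_volume_at <- function(spec, phase) {
  vp <- spec$volume_params
  cosine_track(phase,
               c(0, PH_T_MAX_FRAC, vp$t_preac_frac, vp$t_min_frac, 1),
               c(vp$v_min_ml, vp$v_max_ml, vp$v_preac_ml, vp$v_min_ml,
                 vp$v_min_ml))
}

# Temporal speed envelope (cm/s, spatial-mean scale) at cycle phase.
envelope_at <- function(spec, phase) {
  ve <- spec$velocity_params
  if (!is.null(ve$constant_cmps)) {
    return(rep(ve$constant_cmps, length(phase)))
  }
  phase <- phase %% 1
  b <- ve$baseline_cmps
  bump <- function(centre, width) {
    u <- (phase - centre) / width
    ifelse(abs(u) < 1, cos(pi * u / 2)^2, 0)
  }
  vp <- spec$volume_params
  a_centre <- (vp$t_preac_frac + vp$t_min_frac) / 2
  b +
    (ve$systolic_cmps - b) * bump(PH_T_MAX_FRAC / 2, PH_W_SYS) +
    (ve$e_peak_cmps - b) * bump(PH_E_PEAK_FRAC, PH_W_E) +
    (ve$a_peak_cmps - b) * bump(a_centre, PH_W_A)
}

# Prescribed global longitudinal strain (%) at cycle phase: zero at the
# R-wave (ventricular end-diastole), reservoir peak at end-systole,
# conduit descent to the active-emptying value at pre-ac, back to zero.
strain_at <- function(spec, phase) {
  sp <- spec$strain_params
  vp <- spec$volume_params
  cosine_track(phase,
               c(0, PH_T_MAX_FRAC, vp$t_preac_frac, vp$t_min_frac, 1),
               c(0, sp$reservoir_pct, sp$active_pct, 0, 0))
}

phantom_frame_times <- function(spec) {
  (seq_len(spec$n_frames) - 1) * spec$rr_coverage * spec$rr_ms / spec$n_frames
}

phantom_timings <- function(spec) {
  t_end <- spec$rr_coverage * spec$rr_ms
  vp <- spec$volume_params
  cardiac_timings(
    systole_ms = c(0, PH_T_MAX_FRAC * spec$rr_ms),
    diastole_ms = c(PH_T_MAX_FRAC * spec$rr_ms, t_end),
    t_e_peak_ms = PH_E_PEAK_FRAC * spec$rr_ms,
    t_a_peak_ms = (vp$t_preac_frac + vp$t_min_frac) / 2 * spec$rr_ms,
    t_preac_ms = vp$t_preac_frac * spec$rr_ms,
    rr_ms = spec$rr_ms
  )
}

#' Analytic LA volume curve of a phantom
#'
#' Samples the phantom's smooth periodic volume curve at the flow frame
#' times. The curve attains `v_max_ml` once at end-ventricular systole,
#' descends through a pre-ac plateau at phase `t_preac_frac`, and reaches
#' `v_min_ml` after atrial contraction.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `volume_curve` (see [volume_curve_from_values()]).
#' @export
make_volume_curve <- function(spec) {
  times <- phantom_frame_times(spec)
  vols <- la_volume_at(spec, times / spec$rr_ms)
  volume_curve_from_values(times, vols)
}

# Ellipsoid semi-axis a (mm) from volume (mL): V = 4/3 pi * a^2 * (elong a)
ellipsoid_a_mm <- function(v_ml) {
  (3 * v_ml * 1000 / (4 * pi * PH_ELONG))^(1 / 3)
}

#' Generate a synthetic dynamic-atrium 4D-flow dataset
#'
#' Builds the velocity field, LA and LA-appendage masks, cardiac timings,
#' tracked boundary contours (2- and 4-chamber views) and ground-truth
#' metrics from a [phantom_spec()]. Identical spec and seed reproduce the
#' dataset bit-exactly.
#'
#' @param spec a [phantom_spec()].
#' @return list of class `phantom_dataset` with elements `field`,
#'   `mask_la`, `mask_laa`, `timings`, `contours`, `truth`, `spec`.
#' @export
make_phantom <- function(spec) {
  dims <- spec$grid_dims
  sp_mm <- spec$voxel_spacing_mm
  nt <- spec$n_frames
  times <- phantom_frame_times(spec)
  phases <- times / spec$rr_ms
  co <- grid_coords(dims, sp_mm)
  c0 <- (dims - 1) * sp_mm / 2
  vols <- la_volume_at(spec, phases)
  a_t <- ellipsoid_a_mm(vols)
  a_max <- ellipsoid_a_mm(spec$volume_params$v_max_ml)

  ap <- spec$appendage_params
  r_laa <- ap$radius_mm
  off <- ap$centre_offset_mm
  if (is.null(off)) off <- c(a_max + 0.6 * r_laa, 0, 0)
  laa_c <- c0 + off

  extent <- (dims - 1) * sp_mm
  lo <- c0 - c(a_max, a_max, PH_ELONG * a_max)
  hi <- c0 + c(a_max, a_max, PH_ELONG * a_max)
  lo <- pmin(lo, laa_c - r_laa)
  hi <- pmax(hi, laa_c + r_laa)
  if (any(lo < sp_mm) || any(hi > extent - sp_mm)) {
    stop_la("la_geometry_error",
            "grid too small to contain the atrium and appendage geometry")
  }

  dist_laa2 <- (co$x - laa_c[1])^2 + (co$y - laa_c[2])^2 + (co$z - laa_c[3])^2
  in_sphere <- dist_laa2 <= r_laa^2

  mask_la <- array(FALSE, dim = c(dims, nt))
  mask_laa <- array(FALSE, dim = c(dims, nt))
  for (t in seq_len(nt)) {
    q <- ((co$x - c0[1]) / a_t[t])^2 + ((co$y - c0[2]) / a_t[t])^2 +
      ((co$z - c0[3]) / (PH_ELONG * a_t[t]))^2
    in_ellip <- q <= 1
    mask_la[, , , t] <- in_ellip & !in_sphere
    mask_laa[, , , t] <- in_sphere & !in_ellip
  }
  if (any(apply(mask_laa, 4, sum) == 0L)) {
    stop_la("la_geometry_error", "appendage lobe fully swallowed by the LA")
  }

  env <- envelope_at(spec, phases)
  h <- spec$velocity_params$spatial_heterogeneity

  out <- with_local_seed(spec$seed, {
    if (h > 0) {
      sdlog <- sqrt(log(1 + h^2))
      s_field <- array(stats::rlnorm(prod(dims), meanlog = -sdlog^2 / 2,
                                     sdlog = sdlog), dim = dims)
    } else {
      s_field <- array(1, dim = dims)
    }
    # smooth direction template under a random rotation; metrics use the
    # magnitude only, so this choice is cosmetic
    ph <- runif(3, 0, 2 * pi)
    dx <- 1 + 0.8 * sin(2 * pi * co$z / max(co$z) + ph[1])
    dy <- 1 + 0.8 * sin(2 * pi * co$x / max(co$x) + ph[2])
    dz <- 1 + 0.8 * sin(2 * pi * co$y / max(co$y) + ph[3])
    rot <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    nrm <- sqrt(dx^2 + dy^2 + dz^2)
    d1 <- (rot[1, 1] * dx + rot[1, 2] * dy + rot[1, 3] * dz) / nrm
    d2 <- (rot[2, 1] * dx + rot[2, 2] * dy + rot[2, 3] * dz) / nrm
    d3 <- (rot[3, 1] * dx + rot[3, 2] * dy + rot[3, 3] * dz) / nrm

    sp_true <- array(0, dim = c(dims, nt))
    for (t in seq_len(nt)) {
      sc <- array(0, dim = dims)
      sc[mask_la[, , , t]] <- env[t]
      sc[mask_laa[, , , t]] <- env[t] * ap$velocity_scale
      sp_true[, , , t] <- sc * s_field
    }

    v <- array(0, dim = c(dims, 3, nt))
    offs <- vector("list", 3)
    for (cc in 1:3) {
      p <- spec$offset_plane[cc, ]
      offs[[cc]] <- p[1] + p[2] * co$x + p[3] * co$y + p[4] * co$z
    }
    dirs <- list(d1, d2, d3)
    for (t in seq_len(nt)) {
      for (cc in 1:3) {
        comp <- sp_true[, , , t] * dirs[[cc]] + offs[[cc]]
        if (spec$noise_sd_cmps > 0) {
          comp <- comp + rnorm(length(comp), sd = spec$noise_sd_cmps)
        }
        v[, , , cc, t] <- comp
      }
    }
    list(v = v, sp_true = sp_true)
  })

  field <- velocity_field(out$v, sp_mm, times, spec$rr_ms, venc_cmps = 100)
  m_la <- roi_mask(mask_la, "LA", sp_mm)
  m_laa <- roi_mask(mask_laa, "LAA", sp_mm)
  timings <- phantom_timings(spec)

  contours <- phantom_contours(spec)
  truth <- phantom_truth(spec, out$sp_true, list(LA = m_la, LAA = m_laa),
                         times, timings, vols)

  structure(list(field = field, mask_la = m_la, mask_laa = m_laa,
                 timings = timings, contours = contours, truth = truth,
                 spec = spec),
            class = "phantom_dataset")
}

# Tracked-contour generator: per view an open semicircular polyline whose
# arc length follows L(t) = L0 (1 + gls(t)/100); endpoints are the mitral
# annulus leading edges. Cine frames cover the full R-R interval.
phantom_contours <- function(spec, n_cine = 30L, n_points = 48L) {
  l0 <- c("2ch" = 175, "4ch" = 190)
  times <- (seq_len(n_cine) - 1) * spec$rr_ms / n_cine
  gls <- strain_at(spec, times / spec$rr_ms)
  theta <- pi * (seq_len(n_points) - 1) / (n_points - 1)
  rows <- list()
  for (view in names(l0)) {
    for (f in seq_len(n_cine)) {
      r <- l0[[view]] * (1 + gls[f] / 100) / pi
      rows[[length(rows) + 1]] <- data.frame(
        frame = f, view = view, point_index = seq_len(n_points),
        x_mm = r * cos(theta), y_mm = r * sin(theta))
    }
  }
  contour_sequence(do.call(rbind, rows), times_ms = times)
}

# Ground-truth metrics from the noiseless, offset-free speed array.
# Vectorized direct computation, kept separate from the flow_metrics module.
phantom_truth <- function(spec, sp_true, masks, times, timings, vols) {
  nt <- length(times)
  metrics <- lapply(masks, function(mk) {
    mean_curve <- numeric(nt)
    ke_curve <- numeric(nt)
    n_below <- 0; n_tot <- 0
    vvox_ml <- prod(spec$voxel_spacing_mm) / 1000
    for (t in seq_len(nt)) {
      sel <- mk$m[, , , t]
      sp_t <- sp_true[, , , t][sel]
      mean_curve[t] <- mean(sp_t)
      ke_curve[t] <- 0.5 * 1.025 * vvox_ml * sum(sp_t^2) * 1e-4
      n_below <- n_below + sum(sp_t < 10)
      n_tot <- n_tot + length(sp_t)
    }
    win <- function(curve, w) {
      idx <- switch(w,
        rr = seq_len(nt),
        systole = which(times >= timings$systole_ms[1] &
                        times < timings$systole_ms[2]),
        diastole = which(times >= timings$diastole_ms[1] &
                         times < timings$diastole_ms[2]),
        e = which.min(abs(times - timings$t_e_peak_ms)),
        a = which.min(abs(times - timings$t_a_peak_ms)))
      c(mean = mean(curve[idx]), peak = max(curve[idx]))
    }
    v_max <- spec$volume_params$v_max_ml
    list(
      velocity_mean_rr = win(mean_curve, "rr")[["mean"]],
      velocity_peak_rr = win(mean_curve, "rr")[["peak"]],
      velocity_mean_systole = win(mean_curve, "systole")[["mean"]],
      velocity_peak_systole = win(mean_curve, "systole")[["peak"]],
      velocity_mean_diastole = win(mean_curve, "diastole")[["mean"]],
      velocity_peak_diastole = win(mean_curve, "diastole")[["peak"]],
      velocity_e_wave = win(mean_curve, "e")[["mean"]],
      velocity_a_wave = win(mean_curve, "a")[["mean"]],
      stasis_pct = 100 * n_below / n_tot,
      ke_mean_rr = win(ke_curve, "rr")[["mean"]],
      ke_peak_rr = win(ke_curve, "rr")[["peak"]],
      kei_mean_rr = win(ke_curve, "rr")[["mean"]] * 1000 / v_max,
      kei_peak_rr = win(ke_curve, "rr")[["peak"]] * 1000 / v_max,
      mean_curve = mean_curve, ke_curve = ke_curve
    )
  })
  vp <- spec$volume_params
  sp_s <- spec$strain_params
  list(
    true_volume_curve = vols,
    true_landmark_frames = c(max = which.max(vols), min = which.min(vols),
                             preac = which.min(abs(times - timings$t_preac_ms))),
    true_landmarks_ml = c(v_max = vp$v_max_ml, v_preac = vp$v_preac_ml,
                          v_min = vp$v_min_ml),
    true_metrics = metrics,
    true_strain = list(reservoir = sp_s$reservoir_pct,
                       active = sp_s$active_pct,
                       conduit = sp_s$reservoir_pct - sp_s$active_pct)
  )
}
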