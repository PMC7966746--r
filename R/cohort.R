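# Cohort presets emulating a paroxysmal-AF group and an age-matched
# control group, and the cohort generator built on them.
#
# Preset constants encode the emulated study conditions: group means/SDs of
# heart rate, whole-cycle LA mean velocity, indexed LA volumes (de-indexed
# with a nominal body surface area of 1.9 m^2) and strain phase values. The
# envelope shape ratios and the spatial-heterogeneity CV are the generator's
# own calibration, chosen so that group-level mean velocity, stasis and
# indexed KE of the emulated cohorts land on the emulated study means.

LA4D_BSA_M2 <- 1.9

# group: list(hr, hr_sd, vel, vel_sd, vol (indexed mL/m2: max, preac, min),
# vol_sd, strain (reservoir, active), shape ratios (sys, e, a, base) as
# multiples of the target mean velocity, heterogeneity CV, laa velocity scale
cohort_presets <- function() {
  list(
    control = list(
      hr = 66, hr_sd = 7,
      vel = 16.7, vel_sd = 2.1,
      vol = c(36.6, 26.8, 15.8), vol_sd = c(6.7, 6.4, 5.6),
      strain = c(reservoir = 20.8, active = 6.8),
      shape = c(sys = 1.10, e = 1.70, a = 0.60, base = 0.75),
      heterogeneity = 0.57,
      laa_scale = 0.69
    ),
    af = list(
      hr = 59, hr_sd = 6,
      vel = 13.1, vel_sd = 2.4,
      vol = c(39.6, 29.5, 19.9), vol_sd = c(10.4, 8.4, 7.0),
      strain = c(reservoir = 15.8, active = 6.1),
      shape = c(sys = 1.10, e = 1.70, a = 0.60, base = 0.75),
      heterogeneity = 0.61,
      laa_scale = 0.633
    )
  )
}

rnorm_trunc <- function(n, mean, sd, lo = mean - 2 * sd, hi = mean + 2 * sd) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

# Build a subject spec for a group preset. Subject-level variability enters
# through heart rate, the whole-cycle mean-velocity target (which scales the
# speed envelope), the volume landmarks and the strain phase values; the
# residual group SD of the printed tables is treated as biological,
# spec-level variance (measurement noise is the separate noise_sd term).
draw_subject_spec <- function(preset, spec_seed, vel_target = NULL) {
  with_local_seed(spec_seed, {
    hr <- rnorm_trunc(1, preset$hr, preset$hr_sd)
    rr_ms <- 60000 / hr
    if (is.null(vel_target)) {
      vel_target <- rnorm_trunc(1, preset$vel, preset$vel_sd)
    }
    repeat {
      vols <- rnorm_trunc(3, preset$vol, preset$vol_sd) * LA4D_BSA_M2
      if (vols[1] > vols[2] + 2 && vols[2] > vols[3] + 2 && vols[3] > 10) break
    }
    repeat {
      res <- rnorm_trunc(1, preset$strain[["reservoir"]], 2)
      act <- rnorm_trunc(1, preset$strain[["active"]], 1)
      if (res > act + 2 && act > 1) break
    }
    offset <- rbind(rnorm(3, 0, 1), rnorm(3, 0, 0.01),
                    rnorm(3, 0, 0.01), rnorm(3, 0, 0.01))
    spec <- phantom_spec(
      rr_ms = rr_ms,
      volume_params = list(v_max_ml = vols[1], v_preac_ml = vols[2],
                           v_min_ml = vols[3],
                           t_min_frac = 0.93, t_preac_frac = 0.72),
      velocity_params = list(
        systolic_cmps = preset$shape[["sys"]] * vel_target,
        e_peak_cmps = preset$shape[["e"]] * vel_target,
        a_peak_cmps = preset$shape[["a"]] * vel_target,
        baseline_cmps = preset$shape[["base"]] * vel_target,
        spatial_heterogeneity = preset$heterogeneity,
        constant_cmps = NULL),
      appendage_params = list(velocity_scale = preset$laa_scale,
                              radius_mm = 8.5, centre_offset_mm = NULL),
      strain_params = list(reservoir_pct = res, active_pct = act),
      noise_sd_cmps = 1,
      offset_plane = t(offset),
      seed = spec_seed
    )
    # rescale the envelope so its time average over the covered frames
    # equals the subject's velocity target exactly
    env_mean <- mean(envelope_at(spec, phantom_frame_times(spec) / spec$rr_ms))
    k <- vel_target / env_mean
    for (nm in c("systolic_cmps", "e_peak_cmps", "a_peak_cmps",
                 "baseline_cmps")) {
      spec$velocity_params[[nm]] <- spec$velocity_params[[nm]] * k
    }
    spec
  })
}

#' Preset phantom specification for a study group
#'
#' Draws one subject-level [phantom_spec()] from the `"control"` or `"af"`
#' preset distributions (heart rate, whole-cycle mean velocity target,
#' volume landmarks, strain phases, per-subject residual offset plane).
#'
#' @param group `"control"` or `"af"`.
#' @param seed integer seed for the subject draw.
#' @return a [phantom_spec()].
#' @export
phantom_preset <- function(group = c("control", "af"), seed = 1L) {
  group <- match.arg(group)
  draw_subject_spec(cohort_presets()[[group]], as.integer(seed))
}

#' Generate a labelled two-group phantom cohort
#'
#' Draws `n_ctrl` control-like and `n_af` AF-like subjects from the preset
#' distributions and generates the full dataset for each. The per-subject
#' whole-cycle mean-velocity targets are drawn stratified (group quantiles
#' in random subject order), so that at 30 or more subjects per group the
#' cohort means of LA mean velocity, stasis fraction and indexed KE land
#' on the emulated group means.
#'
#' @param n_af,n_ctrl subjects per group (>= 1).
#' @param seed master seed; per-subject seeds derive from it
#'   deterministically.
#' @return list of subjects, each a list with `id`, `group`, `spec`,
#'   `data` (a [make_phantom()] dataset).
#' @export
make_cohort <- function(n_af, n_ctrl, seed = 1L) {
  if (n_af < 1 || n_ctrl < 1) {
    stop_la("la_parameter_error", "both groups need at least one subject")
  }
  presets <- cohort_presets()
  plan <- with_local_seed(as.integer(seed), {
    out <- list()
    for (g in c("control", "af")) {
      n <- if (g == "control") n_ctrl else n_af
      p <- presets[[g]]
      z <- stats::qnorm((seq_len(n) - 0.5) / n)
      z <- pmin(pmax(z, -2), 2)
      targets <- (p$vel + p$vel_sd * z)[sample.int(n)]
      seeds <- sample.int(.Machine$integer.max - 1L, n)
      for (i in seq_len(n)) {
        out[[length(out) + 1]] <- list(group = g, idx = i,
                                       vel_target = targets[i],
                                       spec_seed = seeds[i])
      }
    }
    out
  })
  lapply(plan, function(s) {
    spec <- draw_subject_spec(presets[[s$group]], s$spec_seed, s$vel_target)
    list(id = sprintf("%s_%02d", s$group, s$idx), group = s$group,
         spec = spec, data = make_phantom(spec))
  })
}
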