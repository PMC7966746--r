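# Hemodynamic read-outs from a corrected velocity field and region masks.

#' Blood density used for kinetic energy (g/mL)
#' @export
LA4D_BLOOD_DENSITY_G_PER_ML <- 1.025

#' Stasis velocity threshold (cm/s)
#' @export
LA4D_STASIS_THRESHOLD_CMPS <- 10

#' Voxelwise speed (velocity magnitude)
#'
#' Three-directional velocity magnitude per voxel per frame,
#' sqrt(vx^2 + vy^2 + vz^2), in cm/s.
#'
#' @param field a [velocity_field()].
#' @return numeric array, dim (nx, ny, nz, n_frames).
#' @export
speed_field <- function(field) {
  v <- field$v
  sp <- sqrt(v[, , , 1, , drop = FALSE]^2 +
             v[, , , 2, , drop = FALSE]^2 +
             v[, , , 3, , drop = FALSE]^2)
  array(sp, dim = dim(v)[c(1, 2, 3, 5)])
}

#' Velocity-time curve: spatial average speed per frame
#'
#' Arithmetic mean of in-mask voxel speeds at each frame, the curve from
#' which windowed mean and peak velocities are read.
#'
#' @param field a [velocity_field()].
#' @param mask a [roi_mask()] on the same grid.
#' @return list of class `velocity_time_curve` with `times_ms`,
#'   `spatial_mean_cmps`, `n_voxels`, `region`.
#' @export
velocity_time_curve <- function(field, mask) {
  check_same_grid(field, mask)
  sp <- speed_field(field)
  nt <- dim(sp)[4]
  means <- numeric(nt)
  nvox <- integer(nt)
  for (t in seq_len(nt)) {
    sel <- mask$m[, , , t]
    nvox[t] <- sum(sel)
    if (nvox[t] == 0L) {
      stop_la("la_region_error", "mask for region %s is empty at frame %d",
              mask$region, t)
    }
    means[t] <- mean(sp[, , , t][sel])
  }
  structure(list(times_ms = field$times_ms, spatial_mean_cmps = means,
                 n_voxels = nvox, region = mask$region),
            class = "velocity_time_curve")
}

# Frame indices belonging to a window. E/A windows are the single frame
# nearest the annotated peak time.
window_frame_idx <- function(times_ms, timings, window) {
  idx <- switch(window,
    RR = seq_along(times_ms),
    systole = which(times_ms >= timings$systole_ms[1] &
                    times_ms < timings$systole_ms[2]),
    diastole = which(times_ms >= timings$diastole_ms[1] &
                     times_ms < timings$diastole_ms[2]),
    E = which.min(abs(times_ms - timings$t_e_peak_ms)),
    A = which.min(abs(times_ms - timings$t_a_peak_ms)),
    stop_la("la_parameter_error", "unknown window '%s'", window)
  )
  if (length(idx) == 0L) {
    stop_la("la_timing_error", "window '%s' contains no frame", window)
  }
  idx
}

#' Windowed mean and peak of a velocity-time curve
#'
#' The mean is the time average of the spatially averaged curve over the
#' frames whose times fall in the window; the peak is the temporal maximum
#' of the same curve. For the E- and A-wave windows both equal the curve
#' value at the single frame nearest the annotated peak time.
#'
#' @param curve a [velocity_time_curve()].
#' @param timings a [cardiac_timings()].
#' @param window one of `"RR"`, `"systole"`, `"diastole"`, `"E"`, `"A"`.
#' @return named numeric: `mean`, `peak` (cm/s).
#' @export
window_velocity_stats <- function(curve, timings, window = "RR") {
  idx <- window_frame_idx(curve$times_ms, timings, window)
  vals <- curve$spatial_mean_cmps[idx]
  c(mean = mean(vals), peak = max(vals))
}

#' Stasis fraction
#'
#' Percentage of the region with flow velocity below a threshold
#' (default 10 cm/s). Two temporal readings are supported:
#' `timefrac` (default) counts in-mask voxel-frame samples below the
#' threshold over all samples; `strict` counts voxels that stay below the
#' threshold at every frame, evaluated on the voxels present in the mask
#' at all frames.
#'
#' @param field a [velocity_field()].
#' @param mask a [roi_mask()].
#' @param threshold_cmps stasis velocity threshold, cm/s.
#' @param mode `"timefrac"` or `"strict"`.
#' @return stasis percentage in `[0, 100]`.
#' @export
stasis_fraction <- function(field, mask,
                            threshold_cmps = LA4D_STASIS_THRESHOLD_CMPS,
                            mode = c("timefrac", "strict")) {
  mode <- match.arg(mode)
  check_positive(threshold_cmps, "threshold_cmps")
  check_same_grid(field, mask)
  sp <- speed_field(field)
  if (sum(mask$m) == 0L) {
    stop_la("la_region_error", "mask for region %s is empty", mask$region)
  }
  if (mode == "timefrac") {
    n_total <- sum(mask$m)
    n_below <- sum(sp < threshold_cmps & mask$m)
    return(100 * n_below / n_total)
  }
  inter <- apply(mask$m, c(1, 2, 3), all)
  if (sum(inter) == 0L) {
    stop_la("la_region_error",
            "no voxel of region %s is present at every frame", mask$region)
  }
  below_all <- apply(sp < threshold_cmps, c(1, 2, 3), all)
  100 * sum(below_all & inter) / sum(inter)
}

#' Kinetic energy-time curve
#'
#' Per frame, KE(t) = sum over in-mask voxels of
#' 0.5 * rho * V_voxel * speed^2, with rho = 1.025 g/mL, the voxel volume
#' in mL and speed in cm/s; the factor 1e-4 converts g cm^2/s^2 to mJ.
#'
#' @param field a [velocity_field()].
#' @param mask a [roi_mask()].
#' @param rho_g_per_ml blood density, g/mL.
#' @return list of class `ke_time_curve` with `times_ms`, `ke_mj`, `region`.
#' @export
kinetic_energy_curve <- function(field, mask,
                                 rho_g_per_ml = LA4D_BLOOD_DENSITY_G_PER_ML) {
  check_same_grid(field, mask)
  sp <- speed_field(field)
  vvox_ml <- prod(field$spacing_mm) / 1000
  nt <- dim(sp)[4]
  ke <- numeric(nt)
  for (t in seq_len(nt)) {
    sel <- mask$m[, , , t]
    if (sum(sel) == 0L) {
      stop_la("la_region_error", "mask for region %s is empty at frame %d",
              mask$region, t)
    }
    ke[t] <- 0.5 * rho_g_per_ml * vvox_ml * sum(sp[, , , t][sel]^2) * 1e-4
  }
  structure(list(times_ms = field$times_ms, ke_mj = ke, region = mask$region),
            class = "ke_time_curve")
}

#' Windowed mean and peak of a KE-time curve
#'
#' Same windowing convention as [window_velocity_stats()], applied to the
#' summed kinetic energy curve.
#'
#' @param ke_curve a [kinetic_energy_curve()].
#' @param timings a [cardiac_timings()].
#' @param window one of `"RR"`, `"systole"`, `"diastole"`, `"E"`, `"A"`.
#' @return named numeric: `mean`, `peak` (mJ).
#' @export
window_ke_stats <- function(ke_curve, timings, window = "RR") {
  idx <- window_frame_idx(ke_curve$times_ms, timings, window)
  vals <- ke_curve$ke_mj[idx]
  c(mean = mean(vals), peak = max(vals))
}

#' Index kinetic energy to the maximum LA volume
#'
#' Converts an absolute KE value (mJ) to an energy density (uJ/mL) by
#' dividing by the maximum LA volume: value * 1000 / v_max.
#'
#' @param value_mj KE in mJ.
#' @param v_max_ml maximum LA volume in mL.
#' @return indexed KE in uJ/mL.
#' @export
index_ke <- function(value_mj, v_max_ml) {
  if (!is.numeric(v_max_ml) || any(v_max_ml <= 0)) {
    stop_la("la_parameter_error", "v_max_ml must be > 0")
  }
  value_mj * 1000 / v_max_ml
}

#' Full flow-metric panel for one region
#'
#' Computes every windowed velocity and KE statistic plus the stasis
#' fraction for a single region, on the windows RR (all available frames),
#' systole, diastole, peak E wave and peak A wave.
#'
#' @param field a [velocity_field()] (offset-corrected).
#' @param mask a [roi_mask()].
#' @param timings a [cardiac_timings()].
#' @param v_max_ml maximum LA volume in mL (for KE indexing).
#' @param stasis_mode `"timefrac"` or `"strict"`.
#' @return named list of class `flow_metrics`; velocity entries in cm/s,
#'   `ke_*` in mJ, `kei_*` in uJ/mL, `stasis_pct` in percent.
#' @export
region_flow_metrics <- function(field, mask, timings, v_max_ml,
                                stasis_mode = "timefrac") {
  vcurve <- velocity_time_curve(field, mask)
  kcurve <- kinetic_energy_curve(field, mask)
  out <- list(region = mask$region)
  for (w in c("RR", "systole", "diastole")) {
    vs <- window_velocity_stats(vcurve, timings, w)
    ks <- window_ke_stats(kcurve, timings, w)
    key <- tolower(if (w == "RR") "rr" else w)
    out[[paste0("velocity_mean_", key)]] <- unname(vs["mean"])
    out[[paste0("velocity_peak_", key)]] <- unname(vs["peak"])
    out[[paste0("ke_mean_", key)]] <- unname(ks["mean"])
    out[[paste0("ke_peak_", key)]] <- unname(ks["peak"])
  }
  out$velocity_e_wave <- unname(window_velocity_stats(vcurve, timings, "E")["mean"])
  out$velocity_a_wave <- unname(window_velocity_stats(vcurve, timings, "A")["mean"])
  out$ke_e_wave <- unname(window_ke_stats(kcurve, timings, "E")["mean"])
  out$ke_a_wave <- unname(window_ke_stats(kcurve, timings, "A")["mean"])
  out$stasis_pct <- stasis_fraction(field, mask, mode = stasis_mode)
  for (nm in grep("^ke_", names(out), value = TRUE)) {
    out[[sub("^ke_", "kei_", nm)]] <- index_ke(out[[nm]], v_max_ml)
  }
  out$v_max_ml <- v_max_ml
  out$rho_g_per_ml <- LA4D_BLOOD_DENSITY_G_PER_ML
  out$stasis_threshold_cmps <- LA4D_STASIS_THRESHOLD_CMPS
  class(out) <- "flow_metrics"
  out
}

#' Flow metrics for several regions at once
#'
#' @param field a [velocity_field()].
#' @param masks named list of [roi_mask()] objects (e.g. LA, LAA).
#' @param timings a [cardiac_timings()].
#' @param v_max_ml maximum LA volume (mL), shared indexing denominator.
#' @param stasis_mode `"timefrac"` or `"strict"`.
#' @return named list of `flow_metrics`, one per region.
#' @export
flow_metrics <- function(field, masks, timings, v_max_ml,
                         stasis_mode = "timefrac") {
  lapply(masks, region_flow_metrics, field = field, timings = timings,
         v_max_ml = v_max_ml, stasis_mode = stasis_mode)
}

#' Paired LA-appendage vs LA differences
#'
#' Per-subject differences (LAA minus LA) of mean/peak whole-cycle
#' velocity and stasis, the contrasts tested with a paired t-test.
#'
#' @param metrics named list with elements `LA` and `LAA`, each a
#'   `flow_metrics` object, or a list of such per-subject lists.
#' @return data frame with one row per subject and columns
#'   `d_velocity_mean_rr`, `d_velocity_peak_rr`, `d_stasis_pct`.
#' @export
compare_la_vs_laa <- function(metrics) {
  if (!is.null(metrics$LA)) metrics <- list(metrics)
  rows <- lapply(metrics, function(m) {
    if (is.null(m$LA) || is.null(m$LAA)) {
      stop_la("la_region_error", "both LA and LAA metrics are required")
    }
    data.frame(
      d_velocity_mean_rr = m$LAA$velocity_mean_rr - m$LA$velocity_mean_rr,
      d_velocity_peak_rr = m$LAA$velocity_peak_rr - m$LA$velocity_peak_rr,
      d_stasis_pct = m$LAA$stasis_pct - m$LA$stasis_pct
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
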