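# LA volume/function decomposition, LV biplane volumes and feature-tracking
# longitudinal strain from tracked contours.

#' Build a volume curve from sampled values
#'
#' @param times_ms frame times (ms).
#' @param volumes_ml volumes (mL), one per frame.
#' @return object of class `volume_curve` with `times_ms`, `volumes_ml`.
#' @export
volume_curve_from_values <- function(times_ms, volumes_ml) {
  if (length(times_ms) != length(volumes_ml)) {
    stop_la("la_parameter_error", "times and volumes must have equal length")
  }
  structure(list(times_ms = as.numeric(times_ms),
                 volumes_ml = as.numeric(volumes_ml)),
            class = "volume_curve")
}

#' LA volume curve from a time-resolved mask
#'
#' `voxel` volumetry counts in-mask voxels times the voxel volume.
#' `slice` volumetry emulates contour-based slice summation: per z-slice
#' area (in-plane voxel count x in-plane voxel area) times the slice
#' increment, which for contiguous stacks with an interslice gap is
#' thickness + gap.
#'
#' @param mask a [roi_mask()].
#' @param times_ms frame times (ms), one per mask frame.
#' @param method `"voxel"` or `"slice"`.
#' @param slice_increment_mm slice thickness + gap (mm); defaults to the
#'   z spacing for `voxel`-equivalent behaviour.
#' @return a `volume_curve`.
#' @export
volume_from_mask <- function(mask, times_ms, method = c("voxel", "slice"),
                             slice_increment_mm = NULL) {
  method <- match.arg(method)
  nt <- dim(mask$m)[4]
  if (length(times_ms) != nt) {
    stop_la("la_parameter_error", "times_ms must match mask frames")
  }
  counts <- apply(mask$m, 4, sum)
  if (any(counts == 0L)) {
    stop_la("la_region_error", "mask for region %s empty at frame %d",
            mask$region, which(counts == 0L)[1])
  }
  if (method == "voxel") {
    vols <- counts * prod(mask$spacing_mm) / 1000
  } else {
    if (is.null(slice_increment_mm)) slice_increment_mm <- mask$spacing_mm[3]
    area_mm2 <- mask$spacing_mm[1] * mask$spacing_mm[2]
    vols <- vapply(seq_len(nt), function(t) {
      slice_counts <- apply(mask$m[, , , t, drop = FALSE], 3, sum)
      sum(slice_counts * area_mm2 * slice_increment_mm) / 1000
    }, numeric(1))
  }
  volume_curve_from_values(times_ms, vols)
}

#' Locate volume-curve landmarks
#'
#' Maximum volume (end-ventricular systole), volume before atrial
#' contraction (curve value at the frame nearest the annotated pre-ac
#' time) and minimum volume.
#'
#' @param curve a `volume_curve`.
#' @param timings a [cardiac_timings()] supplying `t_preac_ms`.
#' @return list: `v_max_ml`, `v_preac_ml`, `v_min_ml` and frame indices
#'   `i_max`, `i_preac`, `i_min`.
#' @export
find_landmarks <- function(curve, timings) {
  i_max <- which.max(curve$volumes_ml)
  i_min <- which.min(curve$volumes_ml)
  i_preac <- which.min(abs(curve$times_ms - timings$t_preac_ms))
  list(v_max_ml = curve$volumes_ml[i_max],
       v_preac_ml = curve$volumes_ml[i_preac],
       v_min_ml = curve$volumes_ml[i_min],
       i_max = i_max, i_preac = i_preac, i_min = i_min)
}

#' LA function decomposition from volume landmarks
#'
#' Reservoir volume = max - min; conduit volume = max - pre-ac; active
#' emptying volume = pre-ac - min. Total function = reservoir x 100 / max;
#' passive function = conduit x 100 / max; booster function =
#' active x 100 / pre-ac.
#'
#' @param landmarks list with `v_max_ml`, `v_preac_ml`, `v_min_ml`
#'   (as from [find_landmarks()]); units propagate (mL or mL/m^2).
#' @return object of class `chamber_function`.
#' @export
chamber_function <- function(landmarks) {
  v_max <- landmarks$v_max_ml
  v_preac <- landmarks$v_preac_ml
  v_min <- landmarks$v_min_ml
  if (!(v_max >= v_preac && v_preac >= v_min)) {
    stop_la("la_landmark_error",
            "landmarks must satisfy v_max >= v_preac >= v_min (got %.3g/%.3g/%.3g)",
            v_max, v_preac, v_min)
  }
  if (v_max <= 0) stop_la("la_parameter_error", "v_max must be > 0")
  active <- v_preac - v_min
  if (v_preac == 0 && active > 0) {
    stop_la("la_parameter_error", "booster function undefined for v_preac = 0")
  }
  structure(list(
    reservoir_ml = v_max - v_min,
    conduit_ml = v_max - v_preac,
    active_ml = active,
    total_pct = (v_max - v_min) * 100 / v_max,
    passive_pct = (v_max - v_preac) * 100 / v_max,
    booster_pct = if (v_preac > 0) active * 100 / v_preac else 0
  ), class = "chamber_function")
}

#' Biplane area-length ventricular volume
#'
#' V = 8 A_2ch A_4ch / (3 pi L), with areas in mm^2 and length in mm,
#' returned in mL.
#'
#' @param area_2ch_mm2,area_4ch_mm2 endocardial (or epicardial) areas in
#'   the two long-axis views, mm^2.
#' @param length_mm long-axis length, mm.
#' @return volume in mL.
#' @export
lv_biplane_area_length <- function(area_2ch_mm2, area_4ch_mm2, length_mm) {
  check_positive(area_2ch_mm2, "area_2ch_mm2")
  check_positive(area_4ch_mm2, "area_4ch_mm2")
  check_positive(length_mm, "length_mm")
  8 * area_2ch_mm2 * area_4ch_mm2 / (3 * pi * length_mm) / 1000
}

#' Left ventricular mass from epi- and endocardial volumes
#'
#' Myocardial density 1.05 g/mL times the wall volume.
#'
#' @param v_epi_ml,v_endo_ml epicardial and endocardial volumes (mL).
#' @param density_g_per_ml myocardial density, g/mL.
#' @return mass in g.
#' @export
lv_mass <- function(v_epi_ml, v_endo_ml, density_g_per_ml = 1.05) {
  if (v_epi_ml < v_endo_ml) {
    stop_la("la_parameter_error", "epicardial volume must be >= endocardial")
  }
  density_g_per_ml * (v_epi_ml - v_endo_ml)
}

#' Ejection fraction
#'
#' @param edv_ml,esv_ml end-diastolic and end-systolic volumes (mL).
#' @return EF in percent.
#' @export
ejection_fraction <- function(edv_ml, esv_ml) {
  if (!(edv_ml >= esv_ml && esv_ml >= 0 && edv_ml > 0)) {
    stop_la("la_parameter_error", "volumes must satisfy edv >= esv >= 0, edv > 0")
  }
  (edv_ml - esv_ml) * 100 / edv_ml
}

polyline_length <- function(x, y) {
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Global longitudinal strain and strain-rate curves from tracked contours
#'
#' Per view, L(t) is the polyline arc length of the tracked boundary;
#' strain(t) = 100 (L(t) - L(ref)) / L(ref) with the reference frame at
#' ventricular end-diastole. The global curve averages the 2- and
#' 4-chamber views pointwise in time. The strain rate is the centred
#' finite difference of strain/100 over time (one-sided at the ends), in
#' 1/s, optionally after a width-3 moving-average smoothing of the strain
#' curve.
#'
#' @param contours a [contour_sequence()] with `times_ms`.
#' @param reference_frame index of the zero-strain reference frame.
#' @param smooth logical, apply width-3 moving average before
#'   differentiation.
#' @return object of class `strain_curves` with `times_ms`, `gls_pct`,
#'   `strain_rate_per_s`, `per_view`.
#' @export
gls_curve <- function(contours, reference_frame = 1L, smooth = FALSE) {
  pts <- contours$points
  frames <- sort(unique(pts$frame))
  times <- contours$times_ms
  if (is.null(times)) {
    stop_la("la_format_error", "contour sequence carries no frame times")
  }
  per_view <- sapply(contours$views, function(v) {
    vapply(frames, function(f) {
      p <- pts[pts$view == v & pts$frame == f, ]
      p <- p[order(p$point_index), ]
      polyline_length(p$x_mm, p$y_mm)
    }, numeric(1))
  })
  strain_view <- 100 * sweep(per_view, 2, per_view[reference_frame, ], "/") - 100
  gls <- rowMeans(strain_view)
  s <- gls
  if (smooth) {
    n <- length(s)
    s <- vapply(seq_len(n), function(i) {
      mean(s[max(1, i - 1):min(n, i + 1)])
    }, numeric(1))
  }
  n <- length(s)
  rate <- numeric(n)
  tsec <- times / 1000
  for (i in seq_len(n)) {
    lo <- max(1, i - 1); hi <- min(n, i + 1)
    rate[i] <- (s[hi] - s[lo]) / 100 / (tsec[hi] - tsec[lo])
  }
  structure(list(times_ms = times, gls_pct = gls, strain_rate_per_s = rate,
                 per_view = strain_view, reference_frame = reference_frame),
            class = "strain_curves")
}

#' Atrial strain phases and strain-rate peaks
#'
#' Reservoir strain is the peak of the strain curve; active-emptying
#' strain is the curve value at the pre-ac time; conduit strain is their
#' difference (reservoir = conduit + active by construction). Conduit and
#' active values are emptying magnitudes reported as positive numbers
#' under the negative-sign convention. Strain-rate peaks: peak positive =
#' maximum rate; peak early negative = magnitude of the most negative rate
#' between the strain peak and pre-ac; peak late negative = magnitude of
#' the most negative rate from pre-ac to the end of the cycle.
#'
#' @param curves a [gls_curve()] result.
#' @param timings a [cardiac_timings()] supplying `t_preac_ms`.
#' @return list with `reservoir_strain`, `conduit_strain`,
#'   `active_strain` (%) and `peak_positive`, `peak_early_negative`,
#'   `peak_late_negative` (1/s).
#' @export
strain_phases <- function(curves, timings) {
  s <- curves$gls_pct
  t <- curves$times_ms
  i_peak <- which.max(s)
  i_preac <- which.min(abs(t - timings$t_preac_ms))
  reservoir <- s[i_peak]
  active <- s[i_preac]
  early_idx <- seq_len(length(s))[t > t[i_peak] & t <= timings$t_preac_ms]
  late_idx <- seq_len(length(s))[t >= timings$t_preac_ms]
  if (length(early_idx) == 0L || length(late_idx) == 0L) {
    stop_la("la_timing_error",
            "empty sub-window between strain peak and pre-ac")
  }
  rate <- curves$strain_rate_per_s
  early_min <- min(rate[early_idx])
  late_min <- min(rate[late_idx])
  if (early_min >= 0 || late_min >= 0) {
    stop_la("la_timing_error",
            "no negative strain rate in an emptying window (monotone strain?)")
  }
  list(reservoir_strain = reservoir,
       conduit_strain = reservoir - active,
       active_strain = active,
       peak_positive = max(rate),
       peak_early_negative = -early_min,
       peak_late_negative = -late_min)
}
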