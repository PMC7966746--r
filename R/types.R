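#' Construct a time-resolved 3-directional velocity field
#'
#' Container for 4D-flow velocity data on a regular voxel grid. Velocities
#' are stored as a 5-D array indexed (i, j, k, component, frame) with the
#' three components along x, y, z in cm/s. World coordinates follow a
#' diagonal affine: voxel (i, j, k) sits at ((i-1) dx, (j-1) dy, (k-1) dz)
#' mm. Frame times are milliseconds from the R-wave.
#'
#' @param v numeric array, dim (nx, ny, nz, 3, n_frames), cm/s.
#' @param spacing_mm positive length-3 numeric, voxel spacing in mm.
#' @param times_ms strictly increasing frame times in `[0, rr_ms)`.
#' @param rr_ms R-R interval in ms.
#' @param venc_cmps velocity encoding sensitivity in cm/s.
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(v, spacing_mm, times_ms, rr_ms, venc_cmps = 100) {
  if (!is.array(v) || length(dim(v)) != 5 || dim(v)[4] != 3) {
    stop_la("la_format_error",
            "velocities must be a 5-D array (nx, ny, nz, 3, n_frames)")
  }
  if (any(!is.finite(v))) stop_la("la_format_error", "non-finite velocities")
  check_positive(spacing_mm, "spacing_mm")
  if (length(spacing_mm) != 3) {
    stop_la("la_parameter_error", "spacing_mm must have length 3")
  }
  check_positive(rr_ms, "rr_ms")
  check_positive(venc_cmps, "venc_cmps")
  if (length(times_ms) != dim(v)[5] || any(diff(times_ms) <= 0) ||
      any(times_ms < 0) || any(times_ms >= rr_ms)) {
    stop_la("la_format_error",
            "times_ms must be strictly increasing within [0, rr_ms) and match frames")
  }
  structure(list(v = v, spacing_mm = as.numeric(spacing_mm),
                 times_ms = as.numeric(times_ms), rr_ms = rr_ms,
                 venc_cmps = venc_cmps),
            class = "velocity_field")
}

#' Construct a time-resolved region-of-interest mask
#'
#' Boolean occupancy of a named region (e.g. LA, LAA) per frame, on the
#' same grid as the paired velocity field.
#'
#' @param m logical array, dim (nx, ny, nz, n_frames).
#' @param region region name, e.g. `"LA"`, `"LAA"`.
#' @param spacing_mm voxel spacing in mm (length 3).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(m, region, spacing_mm) {
  if (!is.array(m) || length(dim(m)) != 4) {
    stop_la("la_format_error", "mask must be a 4-D logical array")
  }
  storage.mode(m) <- "logical"
  check_positive(spacing_mm, "spacing_mm")
  structure(list(m = m, region = as.character(region),
                 spacing_mm = as.numeric(spacing_mm)),
            class = "roi_mask")
}

#' Cardiac timing annotations
#'
#' Systole/diastole windows (half-open, ms from the R-wave) and the timing
#' landmarks used for windowed flow statistics: peak E wave, peak A wave,
#' and the instant before atrial contraction (pre-ac).
#'
#' @param systole_ms,diastole_ms length-2 numerics, half-open `[t0, t1)`.
#' @param t_e_peak_ms,t_a_peak_ms peak E- and A-wave times (ms).
#' @param t_preac_ms time immediately before atrial contraction (ms).
#' @param rr_ms R-R interval (ms).
#' @return An object of class `cardiac_timings`.
#' @export
cardiac_timings <- function(systole_ms, diastole_ms, t_e_peak_ms,
                            t_a_peak_ms, t_preac_ms, rr_ms) {
  check_positive(rr_ms, "rr_ms")
  for (w in list(systole_ms, diastole_ms)) {
    if (length(w) != 2 || w[1] >= w[2] || w[1] < 0 || w[2] > rr_ms) {
      stop_la("la_timing_error", "windows must be ordered within [0, rr_ms]")
    }
  }
  if (max(systole_ms[1], diastole_ms[1]) < min(systole_ms[2], diastole_ms[2])) {
    stop_la("la_timing_error", "systole and diastole windows overlap")
  }
  if (t_e_peak_ms >= t_a_peak_ms) {
    stop_la("la_timing_error", "E-wave peak must precede A-wave peak")
  }
  if (t_preac_ms > t_a_peak_ms) {
    stop_la("la_timing_error", "pre-ac time must not follow the A-wave peak")
  }
  structure(list(systole_ms = as.numeric(systole_ms),
                 diastole_ms = as.numeric(diastole_ms),
                 t_e_peak_ms = t_e_peak_ms, t_a_peak_ms = t_a_peak_ms,
                 t_preac_ms = t_preac_ms, rr_ms = rr_ms),
            class = "cardiac_timings")
}

#' Tracked chamber boundary contours
#'
#' Ordered open polylines per cine frame and long-axis view. The polyline
#' runs from one mitral annulus leading edge around the chamber to the
#' other, so the chord between the first and last points is the annulus
#' line separating atrium from ventricle. Point correspondence is
#' maintained across frames (same point count per view).
#'
#' @param points data frame with columns `frame`, `view`, `point_index`,
#'   `x_mm`, `y_mm`.
#' @param times_ms frame times in ms (one per frame), or `NULL`.
#' @param views required views; defaults to 2- and 4-chamber.
#' @return An object of class `contour_sequence`.
#' @export
contour_sequence <- function(points, times_ms = NULL,
                             views = c("2ch", "4ch")) {
  need <- c("frame", "view", "point_index", "x_mm", "y_mm")
  if (!all(need %in% names(points))) {
    stop_la("la_format_error", "contour table must have columns: %s",
            paste(need, collapse = ", "))
  }
  missing_views <- setdiff(views, unique(points$view))
  if (length(missing_views)) {
    stop_la("la_format_error", "missing contour view(s): %s",
            paste(missing_views, collapse = ", "))
  }
  frames <- sort(unique(points$frame))
  for (v in views) {
    pv <- points[points$view == v, ]
    counts <- table(pv$frame)
    if (length(unique(as.integer(counts))) != 1) {
      stop_la("la_tracking_error",
              "point count varies across frames in view %s", v)
    }
    if (as.integer(counts[1]) < 16) {
      stop_la("la_format_error", "view %s has fewer than 16 points", v)
    }
    if (!identical(sort(unique(pv$frame)), frames)) {
      stop_la("la_format_error", "view %s does not cover all frames", v)
    }
  }
  if (!is.null(times_ms) && length(times_ms) != length(frames)) {
    stop_la("la_format_error", "times_ms length must equal number of frames")
  }
  points <- points[order(points$view, points$frame, points$point_index), ]
  rownames(points) <- NULL
  structure(list(points = points, times_ms = times_ms, views = views),
            class = "contour_sequence")
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$v)
  cat(sprintf("<velocity_field> %dx%dx%d voxels, %d frames, spacing %s mm, RR %.0f ms, VENC %g cm/s\n",
              d[1], d[2], d[3], d[5],
              paste(signif(x$spacing_mm, 3), collapse = "x"),
              x$rr_ms, x$venc_cmps))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  d <- dim(x$m)
  cat(sprintf("<roi_mask> region %s, %dx%dx%d voxels, %d frames, %d-%d voxels/frame\n",
              x$region, d[1], d[2], d[3], d[4],
              min(apply(x$m, 4, sum)), max(apply(x$m, 4, sum))))
  invisible(x)
}
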