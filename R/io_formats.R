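# On-disk formats: NIfTI velocity/mask volumes, CSV contour tables,
# JSON timings/spec/metric reports.
#
# Conventions: one scalar 4D NIfTI volume per velocity component (frame as
# 4th axis), world units mm with a diagonal affine, velocities in cm/s,
# masks 0/1; voxel indices 0-based in world-coordinate formulas; time in ms
# from the R-wave; intervals half-open.

#' Convert a phase image to a velocity component
#'
#' Standard linear phase-contrast scaling: v = VENC * phase / pi, so a
#' phase of +/- pi maps to +/- VENC.
#'
#' @param phase numeric, radians in `[-pi, pi]`.
#' @param venc_cmps velocity encoding sensitivity, cm/s.
#' @return velocity in cm/s, same shape as `phase`.
#' @export
phase_to_velocity <- function(phase, venc_cmps) {
  check_positive(venc_cmps, "venc_cmps")
  if (any(abs(phase) > pi + 1e-12)) {
    stop_la("la_range_error", "phase values outside [-pi, pi]")
  }
  venc_cmps * phase / pi
}

#' Write a velocity field as three NIfTI volumes plus a JSON side-car
#'
#' Writes `vx.nii.gz`, `vy.nii.gz`, `vz.nii.gz` (4D, frame as 4th axis,
#' cm/s) and `flow_meta.json` carrying frame times, R-R interval and VENC.
#'
#' @param field a [velocity_field()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_velocity_field <- function(field, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("vx.nii.gz", "vy.nii.gz", "vz.nii.gz"))
  for (cc in 1:3) {
    img <- RNifti::asNifti(array(field$v[, , , cc, ], dim = dim(field$v)[c(1:3, 5)]),
                           pixdim = c(field$spacing_mm, 1))
    RNifti::writeNifti(img, paths[cc])
  }
  meta <- list(times_ms = field$times_ms, rr_ms = field$rr_ms,
               venc_cmps = field$venc_cmps,
               voxel_spacing_mm = field$spacing_mm)
  meta_path <- file.path(dir, "flow_meta.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, meta_path))
}

#' Read a velocity field from three NIfTI volumes and a JSON side-car
#'
#' @param paths character(3): the x, y, z component volumes.
#' @param meta path to the JSON side-car, or an equivalent list with
#'   `times_ms`, `rr_ms`, `venc_cmps`, `voxel_spacing_mm`.
#' @return a [velocity_field()].
#' @export
read_velocity_field <- function(paths, meta) {
  if (is.character(meta)) meta <- jsonlite::read_json(meta, simplifyVector = TRUE)
  for (k in c("times_ms", "rr_ms", "venc_cmps", "voxel_spacing_mm")) {
    if (is.null(meta[[k]])) {
      stop_la("la_format_error", "flow metadata missing key '%s'", k)
    }
  }
  vols <- lapply(paths, function(p) {
    a <- RNifti::readNifti(p)
    array(as.numeric(a), dim = dim(a))
  })
  dims <- lapply(vols, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop_la("la_format_error", "component volumes have different shapes")
  }
  d <- dims[[1]]
  if (length(d) != 4) {
    stop_la("la_format_error", "component volumes must be 4-D (frame as 4th axis)")
  }
  v <- array(0, dim = c(d[1:3], 3, d[4]))
  for (cc in 1:3) v[, , , cc, ] <- vols[[cc]]
  velocity_field(v, meta$voxel_spacing_mm, meta$times_ms, meta$rr_ms,
                 meta$venc_cmps)
}

#' Write / read a region mask as a 4D NIfTI volume
#'
#' @param mask a [roi_mask()].
#' @param path output file (`.nii` / `.nii.gz`).
#' @return invisibly, the path.
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask$m), dim = dim(mask$m)),
                         pixdim = c(mask$spacing_mm, 1))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask
#' @param region region name to attach.
#' @param spacing_mm voxel spacing (mm); defaults to the NIfTI pixdim.
#' @export
read_mask <- function(path, region, spacing_mm = NULL) {
  a <- RNifti::readNifti(path)
  if (length(dim(a)) != 4) {
    stop_la("la_format_error", "mask volume must be 4-D")
  }
  if (is.null(spacing_mm)) spacing_mm <- RNifti::pixdim(a)[1:3]
  roi_mask(array(as.numeric(a) != 0, dim = dim(a)), region, spacing_mm)
}

#' Write / read cardiac timings as JSON
#'
#' @param timings a [cardiac_timings()].
#' @param path JSON file path.
#' @return invisibly the path; `read_timings` returns a
#'   [cardiac_timings()].
#' @export
write_timings <- function(timings, path) {
  jsonlite::write_json(unclass(timings), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_timings
#' @export
read_timings <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cardiac_timings(x$systole_ms, x$diastole_ms, x$t_e_peak_ms, x$t_a_peak_ms,
                  x$t_preac_ms, x$rr_ms)
}

#' Write tracked contours as a CSV point table
#'
#' Columns: `frame`, `view`, `point_index`, `x_mm`, `y_mm`. Frame times
#' are stored in a JSON side-car next to the CSV
#' (`<stem>_times.json`).
#'
#' @param contours a [contour_sequence()].
#' @param path CSV file path.
#' @return invisibly, the path.
#' @export
write_contours <- function(contours, path) {
  write.csv(contours$points, path, row.names = FALSE)
  if (!is.null(contours$times_ms)) {
    jsonlite::write_json(list(times_ms = contours$times_ms),
                         sub("\\.csv$", "_times.json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read tracked contours from a CSV point table
#'
#' @param path CSV file path (see [write_contours()] for the schema).
#' @param times_ms optional frame times; if `NULL`, the `<stem>_times.json`
#'   side-car is used when present.
#' @param views required views.
#' @return a [contour_sequence()].
#' @export
read_contours <- function(path, times_ms = NULL, views = c("2ch", "4ch")) {
  pts <- read.csv(path, stringsAsFactors = FALSE)
  frames <- unique(pts$frame)
  if (is.unsorted(frames)) {
    stop_la("la_format_error", "contour frames are not ordered")
  }
  if (is.null(times_ms)) {
    side <- sub("\\.csv$", "_times.json", path)
    if (file.exists(side)) {
      times_ms <- jsonlite::read_json(side, simplifyVector = TRUE)$times_ms
    }
  }
  contour_sequence(pts, times_ms = times_ms, views = views)
}

#' Write a flat metric report with unit strings
#'
#' One row per subject, region and metric, with explicit units: cm/s for
#' velocities, % for stasis, mJ for absolute KE, uJ/mL for indexed KE.
#'
#' @param metrics a `flow_metrics` object, a named list of them (regions),
#'   or a list of per-subject region lists.
#' @param path output path; `.json` or `.csv` decides the format.
#' @param subject_ids optional subject identifiers.
#' @return invisibly, the report data frame.
#' @export
write_metrics <- function(metrics, path, subject_ids = NULL) {
  df <- metrics_to_table(metrics, subject_ids)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(df, path, row.names = FALSE)
  }
  invisible(df)
}

metric_unit <- function(key) {
  if (grepl("^velocity", key)) return("cm/s")
  if (grepl("^kei_", key)) return("uJ/mL")
  if (grepl("^ke_", key)) return("mJ")
  if (key == "stasis_pct") return("%")
  if (key == "v_max_ml") return("mL")
  if (key == "rho_g_per_ml") return("g/mL")
  if (key == "stasis_threshold_cmps") return("cm/s")
  ""
}

#' Flatten flow metrics into a long table
#'
#' @inheritParams write_metrics
#' @return data frame with columns `subject`, `region`, `metric`, `value`,
#'   `unit`.
#' @export
metrics_to_table <- function(metrics, subject_ids = NULL) {
  if (inherits(metrics, "flow_metrics")) metrics <- list(metrics)
  if (all(vapply(metrics, inherits, logical(1), "flow_metrics"))) {
    metrics <- list(metrics)
  }
  if (is.null(subject_ids)) subject_ids <- seq_along(metrics)
  rows <- list()
  for (si in seq_along(metrics)) {
    regions <- metrics[[si]]
    for (m in regions) {
      keys <- setdiff(names(m), "region")
      rows[[length(rows) + 1]] <- data.frame(
        subject = subject_ids[si], region = m$region, metric = keys,
        value = vapply(keys, function(k) as.numeric(m[[k]]), numeric(1)),
        unit = vapply(keys, metric_unit, character(1)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a full phantom dataset to a directory
#'
#' Velocity components and masks as NIfTI, contours as CSV, timings plus
#' generative spec and ground truth as JSON.
#'
#' @param dataset a [make_phantom()] result.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_phantom_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_velocity_field(dataset$field, dir)
  write_mask(dataset$mask_la, file.path(dir, "mask_la.nii.gz"))
  write_mask(dataset$mask_laa, file.path(dir, "mask_laa.nii.gz"))
  write_contours(dataset$contours, file.path(dir, "contours.csv"))
  write_timings(dataset$timings, file.path(dir, "timings.json"))
  spec <- dataset$spec
  spec$offset_plane <- as.vector(spec$offset_plane)
  jsonlite::write_json(unclass(spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  truth <- dataset$truth
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a phantom dataset written by [write_phantom_dataset()]
#'
#' @param dir dataset directory.
#' @return list with `field`, `mask_la`, `mask_laa`, `timings`, `contours`.
#' @export
read_phantom_dataset <- function(dir) {
  field <- read_velocity_field(
    file.path(dir, c("vx.nii.gz", "vy.nii.gz", "vz.nii.gz")),
    file.path(dir, "flow_meta.json"))
  list(
    field = field,
    mask_la = read_mask(file.path(dir, "mask_la.nii.gz"), "LA",
                        field$spacing_mm),
    mask_laa = read_mask(file.path(dir, "mask_laa.nii.gz"), "LAA",
                         field$spacing_mm),
    timings = read_timings(file.path(dir, "timings.json")),
    contours = read_contours(file.path(dir, "contours.csv"))
  )
}
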