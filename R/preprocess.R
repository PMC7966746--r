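# Residual velocity-offset correction from stationary tissue and temporal
# co-registration of cine-derived masks to the flow frames.

#' Detect stationary tissue
#'
#' Voxels whose temporal standard deviation of every velocity component is
#' below a threshold, outside any supplied chamber masks, form the static
#' stationary-tissue mask used to assess the residual velocity offset.
#'
#' @param field a [velocity_field()].
#' @param sd_threshold_cmps temporal-sd threshold per component, cm/s.
#' @param exclude optional list of [roi_mask()]s (e.g. LA, LAA); a voxel
#'   inside any of them at any frame is excluded.
#' @return a [roi_mask()] (frame-invariant, replicated over frames) with
#'   region `"stationary"`.
#' @export
detect_stationary_tissue <- function(field, sd_threshold_cmps = 2,
                                     exclude = NULL) {
  check_positive(sd_threshold_cmps, "sd_threshold_cmps")
  d <- dim(field$v)
  nt <- d[5]
  ok <- array(TRUE, dim = d[1:3])
  for (cc in 1:3) {
    comp <- array(field$v[, , , cc, ], dim = c(prod(d[1:3]), nt))
    mu <- rowMeans(comp)
    sdv <- sqrt(rowSums((comp - mu)^2) / (nt - 1))
    ok <- ok & array(sdv < sd_threshold_cmps, dim = d[1:3])
  }
  if (!is.null(exclude)) {
    for (mk in exclude) {
      ever <- apply(mk$m, c(1, 2, 3), any)
      ok <- ok & !ever
    }
  }
  if (sum(ok) == 0L) {
    stop_la("la_stationary_error",
            "no stationary voxel found at sd threshold %.3g cm/s",
            sd_threshold_cmps)
  }
  roi_mask(array(ok, dim = c(d[1:3], nt)), "stationary", field$spacing_mm)
}

#' Fit a linear (first-order) offset plane per velocity component
#'
#' Least-squares fit of the time-averaged velocity of stationary voxels to
#' offset(x, y, z) = a + b x + c y + d z (cm/s, world coordinates in mm),
#' independently per component. This is the spatial linear interpolation
#' of the offset assessed in stationary tissue.
#'
#' @param field a [velocity_field()].
#' @param stationary_mask a [roi_mask()] from [detect_stationary_tissue()].
#' @return object of class `offset_plane_model`: `coefficients` (3x4,
#'   rows = components), `n_stationary_voxels`, `residual_rmse_cmps`
#'   (length 3).
#' @export
fit_offset_plane <- function(field, stationary_mask) {
  d <- dim(field$v)
  sel <- stationary_mask$m[, , , 1]
  n <- sum(sel)
  if (n < 16) {
    stop_la("la_stationary_error",
            "only %d stationary voxels; at least 16 required", n)
  }
  co <- grid_coords(d[1:3], field$spacing_mm)
  X <- cbind(1, co$x[sel], co$y[sel], co$z[sel])
  qx <- qr(X)
  if (qx$rank < 4) {
    stop_la("la_rank_error",
            "stationary voxel positions are degenerate (coplanar/collinear)")
  }
  coefs <- matrix(0, 3, 4,
                  dimnames = list(c("vx", "vy", "vz"), c("a", "b", "c", "d")))
  rmse <- numeric(3)
  nt <- d[5]
  for (cc in 1:3) {
    comp <- array(field$v[, , , cc, ], dim = c(prod(d[1:3]), nt))
    ybar <- rowMeans(comp)[as.vector(sel)]
    beta <- qr.coef(qx, ybar)
    coefs[cc, ] <- beta
    rmse[cc] <- sqrt(mean((ybar - X %*% beta)^2))
  }
  structure(list(coefficients = coefs, n_stationary_voxels = n,
                 residual_rmse_cmps = rmse),
            class = "offset_plane_model")
}

#' Subtract a fitted offset plane from every frame
#'
#' The offset is modeled as time-invariant (eddy-current physics), so the
#' same plane is removed from each frame of each component.
#'
#' @param field a [velocity_field()].
#' @param model an [fit_offset_plane()] result.
#' @return corrected [velocity_field()].
#' @export
correct_offset <- function(field, model) {
  d <- dim(field$v)
  co <- grid_coords(d[1:3], field$spacing_mm)
  v <- field$v
  for (cc in 1:3) {
    p <- model$coefficients[cc, ]
    plane <- p[1] + p[2] * co$x + p[3] * co$y + p[4] * co$z
    for (t in seq_len(d[5])) {
      v[, , , cc, t] <- v[, , , cc, t] - plane
    }
  }
  velocity_field(v, field$spacing_mm, field$times_ms, field$rr_ms,
                 field$venc_cmps)
}

#' Resample cine-timed masks to the flow frame times
#'
#' For each flow frame, takes the mask of the nearest cine frame in time,
#' with wrap-around at the R-R interval; an exact tie between two cine
#' frames resolves to the earlier one.
#'
#' @param mask a [roi_mask()] sampled at `cine_times_ms`.
#' @param cine_times_ms cine frame times (ms), covering `[0, rr_ms)`.
#' @param flow_times_ms flow frame times (ms).
#' @param rr_ms R-R interval (ms).
#' @return a [roi_mask()] with one frame per flow time.
#' @export
resample_masks_to_flow_times <- function(mask, cine_times_ms, flow_times_ms,
                                         rr_ms) {
  if (length(cine_times_ms) == 0L || length(flow_times_ms) == 0L) {
    stop_la("la_parameter_error", "empty time grids")
  }
  if (dim(mask$m)[4] != length(cine_times_ms)) {
    stop_la("la_shape_error", "mask frames do not match cine times")
  }
  pick <- vapply(flow_times_ms, function(tf) {
    delta <- abs(cine_times_ms - tf)
    d <- pmin(delta, rr_ms - delta)
    cand <- which(d == min(d))
    cand[which.min(cine_times_ms[cand])]
  }, integer(1))
  roi_mask(mask$m[, , , pick, drop = FALSE], mask$region, mask$spacing_mm)
}
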