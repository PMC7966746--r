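# Brute-force reference implementation of the flow metrics: explicit loops
# over voxels and frames, no vectorized shortcuts. Intended as an
# equivalence oracle on small fields in tests; the production path is the
# flow_metrics module.

#' Brute-force flow metrics (equivalence oracle)
#'
#' Computes the same panel as [region_flow_metrics()] for each region by
#' direct enumeration of voxel-frame samples. Slow by design; use on small
#' grids.
#'
#' @param field a [velocity_field()].
#' @param masks named list of [roi_mask()]s.
#' @param timings a [cardiac_timings()].
#' @param v_max_ml maximum LA volume (mL) for KE indexing.
#' @param threshold_cmps stasis threshold, cm/s.
#' @return named list per region mirroring `flow_metrics` keys.
#' @export
oracle_metrics <- function(field, masks, timings, v_max_ml,
                           threshold_cmps = 10) {
  d <- dim(field$v)
  if (any(vapply(masks, function(m) !identical(dim(m$m), d[c(1:3, 5)]),
                 logical(1)))) {
    stop_la("la_shape_error", "mask grid does not match field grid")
  }
  nt <- d[5]
  vvox_ml <- prod(field$spacing_mm) / 1000
  times <- field$times_ms
  lapply(masks, function(mk) {
    mean_curve <- numeric(nt)
    ke_curve <- numeric(nt)
    n_below <- 0L
    n_total <- 0L
    for (t in seq_len(nt)) {
      acc <- 0; acc_sq <- 0; n <- 0L
      for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
        if (!mk$m[i, j, k, t]) next
        sp <- sqrt(field$v[i, j, k, 1, t]^2 + field$v[i, j, k, 2, t]^2 +
                   field$v[i, j, k, 3, t]^2)
        acc <- acc + sp
        acc_sq <- acc_sq + sp^2
        n <- n + 1L
        if (sp < threshold_cmps) n_below <- n_below + 1L
        n_total <- n_total + 1L
      }
      if (n == 0L) stop_la("la_region_error", "empty mask frame %d", t)
      mean_curve[t] <- acc / n
      ke_curve[t] <- 0.5 * 1.025 * vvox_ml * acc_sq * 1e-4
    }
    in_win <- function(t, w) {
      switch(w,
        rr = TRUE,
        systole = times[t] >= timings$systole_ms[1] &&
                  times[t] < timings$systole_ms[2],
        diastole = times[t] >= timings$diastole_ms[1] &&
                   times[t] < timings$diastole_ms[2])
    }
    wstats <- function(curve, w) {
      s <- 0; n <- 0L; pk <- -Inf
      for (t in seq_len(nt)) {
        if (!in_win(t, w)) next
        s <- s + curve[t]; n <- n + 1L
        if (curve[t] > pk) pk <- curve[t]
      }
      c(mean = s / n, peak = pk)
    }
    nearest <- function(tt) {
      best <- 1L
      for (t in seq_len(nt)) if (abs(times[t] - tt) < abs(times[best] - tt)) best <- t
      best
    }
    ie <- nearest(timings$t_e_peak_ms)
    ia <- nearest(timings$t_a_peak_ms)
    out <- list(region = mk$region)
    for (w in c("rr", "systole", "diastole")) {
      vs <- wstats(mean_curve, w); ks <- wstats(ke_curve, w)
      out[[paste0("velocity_mean_", w)]] <- vs[["mean"]]
      out[[paste0("velocity_peak_", w)]] <- vs[["peak"]]
      out[[paste0("ke_mean_", w)]] <- ks[["mean"]]
      out[[paste0("ke_peak_", w)]] <- ks[["peak"]]
    }
    out$velocity_e_wave <- mean_curve[ie]
    out$velocity_a_wave <- mean_curve[ia]
    out$ke_e_wave <- ke_curve[ie]
    out$ke_a_wave <- ke_curve[ia]
    out$stasis_pct <- 100 * n_below / n_total
    for (nm in grep("^ke_", names(out), value = TRUE)) {
      out[[sub("^ke_", "kei_", nm)]] <- out[[nm]] * 1000 / v_max_ml
    }
    out
  })
}
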