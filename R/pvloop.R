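#' Cumulative ejected volume from an aortic flow trace
#'
#' Integrates aortic flow (trapezoidal rule) from ejection onset, giving the
#' volume ejected so far at each grid time of the ejection window.  Negative
#' flow samples inside the window (early-diastolic probe artifacts) are
#' clipped to zero and counted.
#'
#' @param flow an [lv_trace] of aortic flow (mL/s) on the beat grid.
#' @param t_ej,t_ee ejection onset and end times (seconds, beat-relative).
#' @return An object of class `lv_ejvol`: `times`, `V_ej` (mL, cumulative,
#'   non-decreasing), `SV` (mL, total), `n_clipped`.
#' @export
ejected_volume <- function(flow, t_ej, t_ee) {
  stopifnot(inherits(flow, "lv_trace"))
  if (t_ee <= t_ej) stop("need t_ee > t_ej")
  tt <- trace_times(flow) - flow$t0
  idx <- which(tt >= t_ej - 1e-12 & tt <= t_ee + 1e-12)
  if (length(idx) < 2L) stop("ejection window contains < 2 samples")
  q <- flow$values[idx]
  n_clipped <- sum(q < 0)
  q <- pmax(q, 0)
  v <- as.numeric(pracma::cumtrapz(tt[idx], q))
  structure(
    list(times = tt[idx], V_ej = v, SV = v[length(v)], n_clipped = n_clipped),
    class = "lv_ejvol")
}

#' End-systolic elastance from the pressure-ejected-volume loop
#'
#' Draws the unique line from the peak isovolumic pressure `(V = 0,
#' P_isomax)` that touches the pressure-ejected-volume loop from above (the
#' end-systolic pressure-stroke volume relation).  Over admissible loop
#' points `(V_i, P_i)` with `V_i` above a small volume floor the candidate
#' slopes are `(P_isomax - P_i) / V_i`; the minimum slope is `E_es` and the
#' minimising point is the end-systolic equilibrium point.
#'
#' @param beat an [lv_beat] providing the pressure samples.
#' @param vol an `lv_ejvol` from [ejected_volume()] on the same beat grid.
#' @param P_isomax peak isovolumic pressure (mmHg); must exceed every loop
#'   pressure.
#' @param v_floor_frac admissible points require `V_i > v_floor_frac * SV`
#'   (default 0.02), guarding the slope singularity at V = 0.
#' @param source label recorded in the result: which flow built the loop.
#' @return An object of class `lv_es`: `E_es` (mmHg/mL), `V_eq`, `P_eq`,
#'   `source`, `n_points`.
#' @export
end_systolic_elastance <- function(beat, vol, P_isomax, v_floor_frac = 0.02,
                                   source = "triangular") {
  stopifnot(inherits(beat, "lv_beat"), inherits(vol, "lv_ejvol"))
  tt <- trace_times(beat$pressure) - beat$pressure$t0
  P <- stats::approx(tt, beat$pressure$values, xout = vol$times, rule = 2)$y
  keep <- vol$V_ej > v_floor_frac * vol$SV
  if (!any(keep)) stop("all loop points excluded by the volume floor")
  V <- vol$V_ej[keep]; P <- P[keep]
  if (P_isomax <= max(P))
    stop("P_isomax (", signif(P_isomax, 5),
         " mmHg) does not exceed the loop pressures (max ",
         signif(max(P), 5), " mmHg)")
  slopes <- (P_isomax - P) / V
  i <- which.min(slopes)
  structure(
    list(E_es = slopes[i], V_eq = V[i], P_eq = P[i],
         P_isomax = P_isomax, source = source, n_points = sum(keep)),
    class = "lv_es")
}

#' @export
print.lv_es <- function(x, ...) {
  cat(sprintf(paste0("<lv_es> E_es = %.4g mmHg/mL (%s flow); equilibrium ",
                     "point (%.4g mL, %.4g mmHg)\n"),
              x$E_es, x$source, x$V_eq, x$P_eq))
  invisible(x)
}
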