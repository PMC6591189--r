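#' Model-predicted LV pressure of the elastance-resistance model
#'
#' The ejecting-beat pressure predicted by a ventricle whose time-varying
#' elastance `P_iso(t) / V_eed` acts on the remaining effective volume and
#' whose internal resistance `P_iso(t) / Q_max` opposes the instantaneous
#' outflow:
#' \deqn{P(t) = P_{iso}(t) [1 - V_{ej}(t)/V_{eed} - Q(t)/Q_{max}]}
#' With no ejection (`Q = 0`, `V_ej = 0`) the prediction is the isovolumic
#' pressure itself; at `Q = Q_max` with no volume yet ejected it is zero,
#' which is what defines `Q_max` as the zero-load flow.
#'
#' @param piso_t isovolumic pressure samples (mmHg).
#' @param flow_t aortic flow samples (mL/s) on the same grid.
#' @param vej_t cumulative ejected volume samples (mL) on the same grid.
#' @param Q_max theoretical maximum flow (mL/s, > 0).
#' @param V_eed effective end-diastolic volume (mL, > 0).
#' @return Predicted pressures (mmHg); may be negative for extreme loads.
#' @export
predict_pressure <- function(piso_t, flow_t, vej_t, Q_max, V_eed) {
  stopifnot(Q_max > 0, V_eed > 0,
            length(piso_t) == length(flow_t),
            length(piso_t) == length(vej_t))
  piso_t * (1 - vej_t / V_eed - flow_t / Q_max)
}

# Cumulative ejected volume placed back on the full beat grid: 0 before the
# window, SV after it.
.vej_on_grid <- function(vol, tt) {
  v <- numeric(length(tt))
  v[tt > vol$times[length(vol$times)]] <- vol$SV
  inside <- tt >= vol$times[1L] & tt <= vol$times[length(vol$times)]
  v[inside] <- stats::approx(vol$times, vol$V_ej, xout = tt[inside],
                             rule = 2)$y
  v
}

#' Fit the elastance-resistance model to a measured beat
#'
#' Estimates `Q_max` and `V_eed` by least squares between the measured and
#' model-predicted pressure over the early-systolic fitting interval
#' `t_ej < t < t_pisomax` (open at both ends), where the deactivation of
#' myocardial shortening is still negligible and the elastance-resistance
#' description holds.  The objective is minimised by a coarse log-spaced
#' grid search followed by bounded quasi-Newton refinement in log
#' parameters.  `E_max = P_isomax / V_eed` and `R_max = P_isomax / Q_max`
#' are derived from the fit by identity.
#'
#' @param beat an [lv_beat] with landmarks set.
#' @param iso an `lv_isofit` from [fit_isovolumic()].
#' @param flow an [lv_trace] of aortic flow on the beat grid (measured or
#'   calibrated triangular).
#' @param vol the matching `lv_ejvol` from [ejected_volume()].
#' @param source `"triangular"` or `"measured"`, recorded in the result.
#' @param t_ej ejection onset bounding the fitting interval; defaults to the
#'   first time of `vol` (the flow's own onset).
#' @param control list: `nq`, `nv` grid resolution (default 24),
#'   `qmax_bounds`, `veed_bounds` as multiples of the peak fitted flow and
#'   of SV (defaults `c(1.05, 50)` and `c(1.05, 20)`), `factr` L-BFGS-B
#'   tolerance (default 10, i.e. ~1e-15 relative).
#'
#' @return An object of class `lv_erfit`: `Q_max`, `V_eed`, `E_max`,
#'   `R_max`, `P_isomax`, `r2`, `SEE_pct` (standard error of the estimate as
#'   a percentage of the peak measured pressure on the interval), `n_fit`,
#'   `source`, `at_bound`, and `fitted` (data frame `t`, `p_meas`,
#'   `p_model`).
#' @export
fit_er_model <- function(beat, iso, flow, vol, source = "triangular",
                         t_ej = NULL, control = list()) {
  stopifnot(inherits(beat, "lv_beat"), inherits(iso, "lv_isofit"),
            inherits(flow, "lv_trace"), inherits(vol, "lv_ejvol"))
  ctrl <- utils::modifyList(
    list(nq = 24L, nv = 24L, qmax_bounds = c(1.05, 50),
         veed_bounds = c(1.05, 20), factr = 10),
    control)
  tt <- trace_times(beat$pressure) - beat$pressure$t0
  if (is.null(t_ej)) t_ej <- vol$times[1L]
  if (!(t_ej < iso$t_pisomax))
    stop("fitting interval empty: t_ej >= t_pisomax")
  mask <- tt > t_ej & tt < iso$t_pisomax
  if (sum(mask) < 8L)
    stop("need >= 8 samples strictly inside (t_ej, t_pisomax), got ",
         sum(mask))

  p_meas <- beat$pressure$values[mask]
  piso <- evaluate_piso(iso, tt[mask])
  q <- pmax(flow$values[mask], 0)
  vej <- .vej_on_grid(vol, tt)[mask]

  SV <- vol$SV
  peak_q <- max(q)
  if (peak_q < 0.01 * SV / beat$T)
    stop("model unidentifiable without ejection (near-zero flow on the ",
         "fitting interval)")

  qb <- ctrl$qmax_bounds * peak_q
  vb <- ctrl$veed_bounds * SV
  sse <- function(lq, lv) {
    pm <- predict_pressure(piso, q, vej, exp(lq), exp(lv))
    sum((p_meas - pm)^2)
  }
  lqs <- seq(log(qb[1]), log(qb[2]), length.out = ctrl$nq)
  lvs <- seq(log(vb[1]), log(vb[2]), length.out = ctrl$nv)
  grid_sse <- outer(lqs, lvs, Vectorize(sse))
  i0 <- arrayInd(which.min(grid_sse), dim(grid_sse))
  opt <- stats::optim(c(lqs[i0[1]], lvs[i0[2]]),
                      fn = function(p) sse(p[1], p[2]),
                      method = "L-BFGS-B",
                      lower = c(log(qb[1]), log(vb[1])),
                      upper = c(log(qb[2]), log(vb[2])),
                      control = list(factr = ctrl$factr, maxit = 500L))
  Q_max <- exp(opt$par[1]); V_eed <- exp(opt$par[2])
  at_bound <- any(abs(opt$par - c(log(qb[1]), log(vb[1]))) < 1e-6) ||
              any(abs(opt$par - c(log(qb[2]), log(vb[2]))) < 1e-6)
  if (at_bound)
    warning("elastance-resistance fit ended at a parameter bound",
            call. = FALSE)

  p_model <- predict_pressure(piso, q, vej, Q_max, V_eed)
  SSE <- sum((p_meas - p_model)^2)
  TSS <- sum((p_meas - mean(p_meas))^2)
  n_fit <- length(p_meas)
  structure(
    list(Q_max = Q_max, V_eed = V_eed,
         E_max = iso$P_isomax / V_eed,
         R_max = iso$P_isomax / Q_max,
         P_isomax = iso$P_isomax,
         r2 = 1 - SSE / TSS,
         SEE_pct = 100 * sqrt(SSE / (n_fit - 2)) / max(p_meas),
         n_fit = n_fit, source = source, at_bound = at_bound,
         fitted = data.frame(t = tt[mask], p_meas = p_meas,
                             p_model = p_model)),
    class = "lv_erfit")
}

#' @export
print.lv_erfit <- function(x, ...) {
  cat(sprintf(paste0("<lv_erfit> (%s flow) Q_max = %.4g mL/s, V_eed = %.4g ",
                     "mL\n  E_max = %.4g mmHg/mL, R_max = %.4g mmHg s/mL; ",
                     "r2 = %.4f, SEE = %.3g%% (n = %d)\n"),
              x$source, x$Q_max, x$V_eed, x$E_max, x$R_max, x$r2,
              x$SEE_pct, x$n_fit))
  invisible(x)
}
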