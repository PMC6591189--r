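#' Select the isovolumic fitting segments of an ejecting beat
#'
#' The isovolumic pressure curve is estimated from the parts of the measured
#' ejecting-beat pressure during which the ventricle is (nearly) isovolumic:
#' the pre-ejection contraction rise and the post-ejection relaxation fall.
#' The contraction set is the samples in `[t_ed, t_ej]` with positive dP/dt
#' and pressure below `cap_frac` of the developed pressure — the cap guards
#' against an overestimated ejection onset admitting early-ejection samples,
#' which sit below the isovolumic curve and bias the fit.  The relaxation
#' set is the samples in `[t_ee, t*]` where `t*` is the first
#' time after end-ejection at which pressure falls below the midpoint
#' between the end-ejection pressure and the end-diastolic pressure (by
#' then the mitral valve is about to open and the limb is no longer purely
#' isovolumic).  dP/dt is taken from the harmonic-truncated beat so the
#' sign test is robust to measurement noise.
#'
#' @param beat an [lv_beat] with landmarks `t_ed < t_ej < t_ee` set.
#' @param n_harmonics harmonics kept when smoothing dP/dt for the sign test.
#' @param cap_frac contraction samples are limited to smoothed pressures
#'   below this fraction of the developed pressure (default 0.6).
#' @return List with data frames `contraction` and `relaxation`, each with
#'   columns `t` (seconds) and `p` (mmHg).
#' @export
select_fit_segments <- function(beat, n_harmonics = 15L, cap_frac = 0.6) {
  stopifnot(inherits(beat, "lv_beat"))
  if (!all(is.finite(c(beat$t_ed, beat$t_ej, beat$t_ee))))
    stop("beat landmarks t_ed, t_ej, t_ee must be set")
  .check_landmarks(beat)
  p <- beat$pressure$values
  tt <- trace_times(beat$pressure) - beat$pressure$t0
  sm <- fourier_truncate(p, n_harmonics)
  dpdt <- spectral_derivative(sm, beat$T, order = 1L)

  p_ed <- stats::approx(tt, p, xout = beat$t_ed, rule = 2)$y
  if (max(sm) - p_ed < 1e-6 * max(abs(p), 1))
    stop("insufficient isovolumic samples (flat or malformed pressure)")
  p_cap <- p_ed + cap_frac * (max(sm) - p_ed)
  in_con <- tt >= beat$t_ed & tt <= beat$t_ej & dpdt > 0 & sm <= p_cap
  p_ee <- stats::approx(tt, p, xout = beat$t_ee, rule = 2)$y
  p_cut <- p_ed + 0.5 * (p_ee - p_ed)
  after_ee <- which(tt >= beat$t_ee)
  below <- after_ee[p[after_ee] < p_cut]
  i_star <- if (length(below)) below[1L] else length(tt)
  in_rel <- tt >= beat$t_ee & seq_along(tt) <= i_star

  if (!any(in_con) || !any(in_rel))
    stop("insufficient isovolumic samples (flat or malformed pressure)")
  list(contraction = data.frame(t = tt[in_con], p = p[in_con]),
       relaxation  = data.frame(t = tt[in_rel], p = p[in_rel]))
}

#' Fit the isovolumic pressure curve
#'
#' Fits the shifted-cosine isovolumic model
#' \deqn{P(t) = P_d + (P_{idmax}/2) [1 - \cos(\omega (t - t_{ed}) + C)]}
#' to the contraction and relaxation segments by Levenberg-Marquardt least
#' squares, with the end-diastolic pressure `P_d` fixed at its measured
#' value and three free parameters (`P_idmax`, `omega`, `C`).  The peak
#' isovolumic pressure is `P_isomax = P_d + P_idmax`, attained at
#' `t_pisomax = t_ed + (pi - C) / omega`.
#'
#' @param segments segment list from [select_fit_segments()], or any list of
#'   data frames with columns `t` and `p`.
#' @param P_d measured LV end-diastolic pressure (mmHg), held fixed.
#' @param t_ed end-diastole time (seconds) used as the phase origin.
#' The search is made robust to the phase-wrap local minima of the periodic
#' cosine by profiling: for fixed (`omega`, `C`) the amplitude is linear and
#' solved in closed form, a deterministic grid places the pressure peak
#' `t_pisomax` between the contraction and relaxation limbs (where the peak
#' of an isovolumic beat must lie) while rejecting solutions whose cosine
#' wraps past a full cycle over the fitted samples, and the grid optimum is
#' polished by Levenberg-Marquardt.
#'
#' @param t_peak optional time of the measured-pressure peak, used to centre
#'   the peak-time grid when the segments are not labelled
#'   contraction/relaxation.
#' @param control list of optimiser settings: `ptol` relative parameter
#'   tolerance (default `1e-8`), `maxiter` (default 500), `n_tpk`, `n_C`
#'   grid resolution (defaults 40 and 21).
#'
#' @return An object of class `lv_isofit`: `P_d`, `P_idmax`, `omega`,
#'   `phase_C`, `t_ed`, `t_pisomax`, `P_isomax`, `rms_residual`,
#'   `n_points_contraction`, `n_points_relaxation`, and `suspect` (TRUE when
#'   the fitted `P_isomax` is below the largest fitted pressure sample,
#'   which is physically implausible).
#' @export
fit_isovolumic <- function(segments, P_d, t_ed, t_peak = NULL,
                           control = list()) {
  ctrl <- utils::modifyList(list(ptol = 1e-8, maxiter = 500L,
                                 n_tpk = 40L, n_C = 21L),
                            control)
  dat <- do.call(rbind, lapply(segments, function(d) d[, c("t", "p")]))
  if (nrow(dat) < 4L) stop("need at least 4 samples to fit 3 parameters")

  # bracket for the peak time: between the end of the contraction limb and
  # the start of the relaxation limb when labelled, otherwise around the
  # largest-pressure sample
  t_last <- max(dat$t)
  if (!is.null(segments$contraction) && !is.null(segments$relaxation) &&
      nrow(segments$relaxation) > 0L) {
    lo <- max(segments$contraction$t)
    hi <- min(segments$relaxation$t)
  } else {
    tp <- if (is.null(t_peak)) dat$t[which.max(dat$p)] else t_peak
    lo <- tp - 0.3 * (tp - t_ed)
    hi <- tp + 0.3 * (tp - t_ed)
  }
  if (!(hi > lo)) {
    mid <- (hi + lo) / 2
    lo <- mid - 0.25 * (mid - t_ed)
    hi <- mid + 0.25 * (mid - t_ed)
  }
  lo <- max(lo, t_ed + 1e-9)

  # profiled grid: amplitude is linear given (omega, C)
  gfun <- function(om, C) (1 - cos(om * (dat$t - t_ed) + C)) / 2
  best <- NULL
  for (tpk in seq(lo, hi, length.out = ctrl$n_tpk)) {
    for (C in seq(-1, 1, length.out = ctrl$n_C)) {
      om <- (pi - C) / (tpk - t_ed)
      if (om <= 0) next
      if (om * (t_last - t_ed) + C > 2 * pi) next   # cosine would wrap
      g <- gfun(om, C)
      den <- sum(g^2)
      if (den <= 0) next
      pid <- max(sum(g * (dat$p - P_d)) / den, 1e-6)
      sse <- sum((dat$p - P_d - pid * g)^2)
      if (is.null(best) || sse < best$sse)
        best <- list(par = c(pid, om, C), sse = sse)
    }
  }
  if (is.null(best)) stop("isovolumic fit: no feasible grid point")

  model <- function(par, t) {
    P_d + (par[1] / 2) * (1 - cos(par[2] * (t - t_ed) + par[3]))
  }
  om0 <- best$par[2]
  polish <- tryCatch(
    minpack.lm::nls.lm(
      par = best$par,
      fn = function(par) dat$p - model(par, dat$t),
      lower = c(1e-6, 0.6 * om0, best$par[3] - 0.5),
      upper = c(Inf, 1.6 * om0, best$par[3] + 0.5),
      control = minpack.lm::nls.lm.control(ptol = ctrl$ptol,
                                           maxiter = ctrl$maxiter)),
    error = function(e) NULL)
  if (is.null(polish))
    stop("isovolumic fit did not converge (grid residual ",
         signif(sqrt(best$sse / nrow(dat)), 4), " mmHg rms)")
  par <- polish$par
  deviance <- polish$deviance
  converged <- polish$info %in% 1:4
  n_con <- if (!is.null(segments$contraction)) nrow(segments$contraction)
           else nrow(dat)
  n_rel <- if (!is.null(segments$relaxation)) nrow(segments$relaxation) else 0L
  out <- structure(
    list(P_d = P_d, P_idmax = par[1], omega = par[2], phase_C = par[3],
         t_ed = t_ed,
         t_pisomax = t_ed + (pi - par[3]) / par[2],
         P_isomax = P_d + par[1],
         rms_residual = sqrt(deviance / nrow(dat)),
         n_points_contraction = n_con, n_points_relaxation = n_rel,
         suspect = (P_d + par[1]) < max(dat$p),
         converged = converged),
    class = "lv_isofit")
  if (out$suspect)
    warning("fitted P_isomax (", signif(out$P_isomax, 5),
            " mmHg) is below the largest fitted pressure sample", call. = FALSE)
  out
}

#' Evaluate a fitted isovolumic pressure curve
#'
#' @param fit an `lv_isofit` from [fit_isovolumic()].
#' @param times numeric vector of times (seconds, beat-relative).
#' @return Pressures in mmHg.
#' @export
evaluate_piso <- function(fit, times) {
  stopifnot(inherits(fit, "lv_isofit"))
  fit$P_d + (fit$P_idmax / 2) *
    (1 - cos(fit$omega * (times - fit$t_ed) + fit$phase_C))
}

#' @export
print.lv_isofit <- function(x, ...) {
  cat(sprintf(paste0("<lv_isofit> P_isomax = %.4g mmHg (P_d = %.3g, ",
                     "P_idmax = %.4g), omega = %.4g rad/s\n"),
              x$P_isomax, x$P_d, x$P_idmax, x$omega))
  cat(sprintf("  t_pisomax = %.4g s, rms residual = %.3g mmHg (%d + %d pts)%s\n",
              x$t_pisomax, x$rms_residual, x$n_points_contraction,
              x$n_points_relaxation,
              if (isTRUE(x$suspect)) " [suspect]" else ""))
  invisible(x)
}
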