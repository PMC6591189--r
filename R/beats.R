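#' One ensemble-averaged pressure beat
#'
#' A single cardiac cycle of left-ventricular pressure on a half-open
#' period-`T` grid `[0, T)`, with the R-wave alignment at index 1 and optional
#' mechanical landmarks: end-diastole `t_ed`, ejection onset `t_ej` and end
#' of ejection `t_ee` (seconds from beat start).
#'
#' @param pressure an [lv_trace] of LV pressure (mmHg) covering exactly one
#'   beat; its `t0` is taken as 0 within the beat.
#' @param T beat period in seconds; defaults to `n * dt` of the trace.
#' @param t_ed,t_ej,t_ee optional landmark times; when all are present they
#'   must satisfy `0 <= t_ed < t_ej < t_ee < T`.
#' @param fiducial index of the R-wave alignment sample (1-based).
#'
#' @return An object of class `lv_beat`.
#' @export
pressure_beat <- function(pressure, T = NULL, t_ed = NA_real_,
                          t_ej = NA_real_, t_ee = NA_real_, fiducial = 1L) {
  stopifnot(inherits(pressure, "lv_trace"))
  n <- length(pressure$values)
  if (is.null(T)) T <- n * pressure$dt
  if (abs(T - n * pressure$dt) > 1e-9 * T)
    stop("beat period T must equal n * dt of the pressure trace")
  b <- structure(
    list(pressure = pressure, T = T, t_ed = t_ed, t_ej = t_ej, t_ee = t_ee,
         fiducial = as.integer(fiducial)),
    class = "lv_beat")
  .check_landmarks(b)
  b
}

.check_landmarks <- function(beat) {
  lm <- c(beat$t_ed, beat$t_ej, beat$t_ee)
  if (all(is.finite(lm))) {
    if (!(0 <= beat$t_ed && beat$t_ed < beat$t_ej && beat$t_ej < beat$t_ee &&
          beat$t_ee < beat$T))
      stop("landmarks must satisfy 0 <= t_ed < t_ej < t_ee < T (got ",
           paste(signif(lm, 5), collapse = ", "), " with T = ",
           signif(beat$T, 5), ")")
  }
  invisible(beat)
}

#' @export
print.lv_beat <- function(x, ...) {
  cat(sprintf("<lv_beat> T = %.4g s, %d samples @ %.4g s\n", x$T,
              length(x$pressure$values), x$pressure$dt))
  if (is.finite(x$t_ed))
    cat(sprintf("  landmarks: t_ed = %.4g, t_ej = %.4g, t_ee = %.4g s\n",
                x$t_ed, x$t_ej, x$t_ee))
  invisible(x)
}

#' Select steady beats and ensemble-average them
#'
#' Splits a continuous pressure recording into beats at the supplied R-wave
#' fiducial times, discards beats whose RR interval deviates by 5% or more
#' from the mean RR of all recorded beats (the steady-state selection rule),
#' linearly resamples each retained beat onto the mean-RR grid, and averages
#' them pointwise in the time domain.
#'
#' @param pressure an [lv_trace] of LV pressure spanning several beats.
#' @param fiducials numeric vector of R-wave times (seconds, increasing); at
#'   least two, i.e. one complete RR interval.
#' @param rr_tol relative RR deviation above which a beat is excluded
#'   (default 0.05).
#'
#' @return A list with components `beat` (an [lv_beat] whose period is the
#'   mean retained RR) and `report`, a list with `n_input`, `n_retained`,
#'   `mean_RR` and `excluded` (data frame of index and reason).
#' @export
select_and_average_beats <- function(pressure, fiducials, rr_tol = 0.05) {
  stopifnot(inherits(pressure, "lv_trace"))
  fiducials <- as.numeric(fiducials)
  if (length(fiducials) < 2L)
    stop("need at least one complete RR interval (two fiducials)")
  if (any(diff(fiducials) <= 0)) stop("fiducials must be strictly increasing")
  rr <- diff(fiducials)
  n_input <- length(rr)
  mean_rr_all <- mean(rr)
  dev <- abs(rr - mean_rr_all) / mean_rr_all
  keep <- dev < rr_tol
  excluded <- data.frame(index = which(!keep),
                         reason = sprintf("RR deviates %.1f%% from mean RR",
                                          100 * dev[!keep]))
  if (!any(keep)) stop("no beats retained by the RR selection rule")

  T <- mean(rr[keep])
  dt <- pressure$dt
  n_out <- max(8L, round(T / dt))
  grid <- (seq_len(n_out) - 1L) * dt
  tt <- trace_times(pressure)
  acc <- numeric(n_out)
  for (j in which(keep)) {
    xout <- fiducials[j] + grid
    acc <- acc + stats::approx(tt, pressure$values, xout = xout,
                               rule = 2)$y
  }
  avg <- acc / sum(keep)
  beat <- pressure_beat(
    lv_trace(avg, dt = dt, t0 = 0, units = pressure$units,
             label = paste0(pressure$label, "_avg")),
    T = n_out * dt)
  list(beat = beat,
       report = list(n_input = n_input, n_retained = sum(keep),
                     mean_RR = T, excluded = excluded))
}

#' Detect R-wave fiducials in an ECG trace
#'
#' Simple threshold-and-refractory peak picker sufficient for clean or mildly
#' noisy ECG: samples above `frac` of the signal range that are local maxima,
#' separated by at least `min_rr` seconds.
#'
#' @param ecg an [lv_trace] of ECG.
#' @param min_rr minimum RR interval in seconds (refractory period).
#' @param frac detection threshold as a fraction of the range above baseline.
#' @return Numeric vector of R-wave times (seconds).
#' @export
find_r_peaks <- function(ecg, min_rr = 0.08, frac = 0.5) {
  stopifnot(inherits(ecg, "lv_trace"))
  v <- ecg$values
  thr <- min(v) + frac * (max(v) - min(v))
  n <- length(v)
  cand <- which(v > thr)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[v[cand] >= v[cand - 1L] & v[cand] >= v[cand + 1L]]
  if (!length(cand)) stop("no R peaks found")
  tt <- trace_times(ecg)
  picks <- integer(0)
  last_t <- -Inf
  for (i in cand) {
    if (tt[i] - last_t >= min_rr) {
      picks <- c(picks, i)
      last_t <- tt[i]
    } else if (length(picks) && v[i] > v[picks[length(picks)]]) {
      picks[length(picks)] <- i   # keep the taller peak within refractory
      last_t <- tt[i]
    }
  }
  tt[picks]
}
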