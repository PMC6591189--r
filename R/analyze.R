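# Default end-diastole landmark: time of the minimum (smoothed) pressure
# preceding the upstroke (the global max of dP/dt).  Falls back to the global
# minimum when the upstroke sits at the very start of the beat.
.default_t_ed <- function(beat, n_harmonics, t_ej) {
  p <- beat$pressure$values
  tt <- (seq_along(p) - 1L) * beat$pressure$dt
  sm <- fourier_truncate(p, n_harmonics)
  dpdt <- spectral_derivative(sm, beat$T, order = 1L)
  i_up <- which.max(dpdt)
  cand <- if (i_up > 2L) seq_len(i_up) else which(tt < t_ej)
  if (!length(cand)) stop("cannot place t_ed before ejection onset")
  win <- p[cand]
  i_min <- cand[max(which(win <= min(win) + 1e-12))]   # last of the minima
  t_ed <- tt[i_min]
  if (t_ed >= t_ej) t_ed <- tt[cand[which.min(win)]]
  if (t_ed >= t_ej) stop("cannot place t_ed before ejection onset")
  t_ed
}

# Ejection window of a measured flow trace: threshold crossing at
# `frac` of peak flow on either side of the peak.
.flow_window <- function(flow, frac = 0.02) {
  q <- flow$values
  tt <- trace_times(flow) - flow$t0
  i_pk <- which.max(q)
  if (q[i_pk] <= 0) stop("measured flow has no positive peak")
  thr <- frac * q[i_pk]
  before <- which(q[seq_len(i_pk)] <= thr)
  i_on <- if (length(before)) max(before) else 1L
  after <- which(q <= thr & seq_along(q) > i_pk)
  i_end <- if (length(after)) min(after) else length(q)
  c(t_ej = tt[i_on], t_ee = tt[i_end])
}

#' Single-beat estimation of LV pumping mechanics
#'
#' Runs the full single-beat pipeline on one averaged pressure beat:
#' triangular-flow landmark location and calibration, isovolumic curve fit,
#' ejected-volume loop, tangent end-systolic elastance, and the
#' elastance-resistance model fit.  When a measured aortic flow is supplied
#' the loop/elastance stages are run twice, once from the measured flow
#' (`mQ`) and once from the pressure-only triangular flow (`triQ`), giving
#' the paired comparison; with pressure alone only `triQ` results exist.
#'
#' @param beat an [lv_beat]; landmarks are derived from the triangular flow
#'   (`t_ej`, `t_ee`) and the pre-upstroke pressure minimum (`t_ed`) when
#'   not already set.
#' @param CO cardiac output in mL/s (calibrates the triangular flow).
#' @param HR heart rate in beats/min.
#' @param flow optional measured aortic flow [lv_trace] on the beat grid.
#' @param config an [lv_config].
#' @return An object of class `lv_analysis`: `beat`, `iso`, `triangle`, and
#'   `results`, a list with elements `triQ` and (if flow was given) `mQ`,
#'   each holding `vol`, `es` and `er`.
#' @export
analyze_beat <- function(beat, CO, HR, flow = NULL, config = lv_config()) {
  stopifnot(inherits(beat, "lv_beat"), CO > 0, HR > 0)
  nh <- config$n_harmonics
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  # pass 1: provisional landmarks from the filtered fourth derivative;
  # trusted landmarks on the beat bypass detection entirely, and the
  # triangle apex then sits at the default fraction of the base
  landmarks_given <- all(is.finite(c(beat$t_ed, beat$t_ej, beat$t_ee)))
  if (landmarks_given) {
    tri_prov <- c(t_onset = beat$t_ej,
                  t_peak = beat$t_ej + 0.22 * (beat$t_ee - beat$t_ej),
                  t_end = beat$t_ee)
    attr(tri_prov, "exact") <- tri_prov
  } else {
    tri_prov <- stage("locate_triangle", locate_triangle(beat, nh))
    exact <- attr(tri_prov, "exact")
    t_ej <- exact[["t_onset"]]
    t_ee <- exact[["t_end"]]
    t_ed <- if (is.finite(beat$t_ed)) beat$t_ed else
      stage("t_ed", .default_t_ed(beat, nh, t_ej))
    beat <- pressure_beat(beat$pressure, T = beat$T, t_ed = t_ed,
                          t_ej = t_ej, t_ee = t_ee, fiducial = beat$fiducial)
  }

  tt <- trace_times(beat$pressure) - beat$pressure$t0
  P_d <- stats::approx(tt, beat$pressure$values, xout = beat$t_ed,
                       rule = 2)$y
  t_peak <- tt[which.max(beat$pressure$values)]
  segs <- stage("select_fit_segments", select_fit_segments(beat, nh))
  iso <- stage("fit_isovolumic",
               fit_isovolumic(segs, P_d = P_d, t_ed = beat$t_ed,
                              t_peak = t_peak,
                              control = list(ptol = config$iso_ptol,
                                             maxiter = config$iso_maxiter,
                                             n_tpk = config$iso_n_tpk,
                                             n_C = config$iso_n_C)))

  # pass 2: refine the ejection onset with the fitted isovolumic curve and
  # rebuild the beat landmarks from the refined triangle
  tri_times <- if (landmarks_given) tri_prov else
    stage("locate_triangle",
          locate_triangle(beat, nh, iso = iso, CO = CO, HR = HR))
  if (!landmarks_given) {
    exact <- attr(tri_times, "exact")
    beat <- pressure_beat(beat$pressure, T = beat$T, t_ed = beat$t_ed,
                          t_ej = exact[["t_onset"]], t_ee = exact[["t_end"]],
                          fiducial = beat$fiducial)
  }
  tri <- stage("calibrate_triangle",
               calibrate_triangle(tri_times, CO, HR, beat$pressure))

  run_source <- function(flow_tr, t_ej, t_ee, source) {
    vol <- stage(paste0("ejected_volume[", source, "]"),
                 ejected_volume(flow_tr, t_ej, t_ee))
    es <- stage(paste0("e_es[", source, "]"),
                end_systolic_elastance(beat, vol, iso$P_isomax,
                                       v_floor_frac = config$v_floor_frac,
                                       source = source))
    er <- stage(paste0("er_fit[", source, "]"),
                fit_er_model(beat, iso, flow_tr, vol, source = source,
                             t_ej = t_ej,
                             control = list(nq = config$er_nq,
                                            nv = config$er_nv,
                                            factr = config$er_factr)))
    list(vol = vol, es = es, er = er)
  }

  results <- list(triQ = run_source(tri$samples, beat$t_ej, beat$t_ee,
                                    "triangular"))
  if (!is.null(flow)) {
    w <- if (landmarks_given) c(t_ej = beat$t_ej, t_ee = beat$t_ee) else
      stage("flow_window", .flow_window(flow, config$flow_onset_frac))
    results$mQ <- run_source(flow, w[["t_ej"]], w[["t_ee"]], "measured")
  }
  structure(
    list(beat = beat, iso = iso, triangle = tri, results = results,
         CO = CO, HR = HR, config = config),
    class = "lv_analysis")
}

#' Analyse a recorded CSV file
#'
#' Reads a waveform record, ensemble-averages beats on the ECG R wave when
#' an ECG channel is present (a record without ECG is treated as a single
#' beat), and runs [analyze_beat()].  A measured-flow channel, when present,
#' is averaged over the same retained beats and produces the paired `mQ`
#' results.
#'
#' @param path CSV record path (see [read_record()] for the format).
#' @param CO cardiac output, mL/s.
#' @param HR heart rate, beats/min.
#' @param config an [lv_config].
#' @return An `lv_analysis` (see [analyze_beat()]) with an extra
#'   `selection` element holding the beat-selection report (or NULL for
#'   single-beat records).
#' @export
analyze_record <- function(path, CO, HR, config = lv_config()) {
  traces <- read_record(path)
  if (!"p_lv" %in% names(traces)) stop("record has no p_lv_mmHg channel")
  selection <- NULL
  if ("ecg" %in% names(traces)) {
    fid <- find_r_peaks(traces$ecg, min_rr = 0.5 * 60 / HR)
    sel <- select_and_average_beats(traces$p_lv, fid, rr_tol = config$rr_tol)
    beat <- sel$beat
    selection <- sel$report
    flow <- if ("q_ao" %in% names(traces)) {
      select_and_average_beats(traces$q_ao, fid,
                               rr_tol = config$rr_tol)$beat$pressure
    }
  } else {
    beat <- pressure_beat(traces$p_lv)
    flow <- if ("q_ao" %in% names(traces)) traces$q_ao
  }
  if (!is.null(flow)) flow$t0 <- 0
  out <- analyze_beat(beat, CO = CO, HR = HR, flow = flow, config = config)
  out$selection <- selection
  out
}

#' Serialise an analysis to the JSON result schema
#'
#' @param analysis an `lv_analysis`.
#' @param path optional output path; when NULL the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
result_json <- function(analysis, path = NULL) {
  stopifnot(inherits(analysis, "lv_analysis"))
  iso <- analysis$iso
  tri <- analysis$triangle
  one_source <- function(res) {
    list(e_es = list(value = res$es$E_es, units = "mmHg/mL"),
         equilibrium_point = list(V = res$es$V_eq, P = res$es$P_eq,
                                  units = c("mL", "mmHg")),
         er_model = list(
           Q_max = list(value = res$er$Q_max, units = "mL/s"),
           V_eed = list(value = res$er$V_eed, units = "mL"),
           E_max = list(value = res$er$E_max, units = "mmHg/mL"),
           R_max = list(value = res$er$R_max, units = "mmHg.s/mL"),
           r2 = res$er$r2, SEE_pct = res$er$SEE_pct, n_fit = res$er$n_fit,
           see_denominator = "peak measured pressure on fitting interval"))
  }
  obj <- list(
    schema_version = "1.0",
    inputs = list(CO = list(value = analysis$CO, units = "mL/s"),
                  HR = list(value = analysis$HR, units = "beats/min")),
    isovolumic = list(
      P_d = list(value = iso$P_d, units = "mmHg"),
      P_idmax = list(value = iso$P_idmax, units = "mmHg"),
      P_isomax = list(value = iso$P_isomax, units = "mmHg"),
      omega = list(value = iso$omega, units = "rad/s"),
      phase_C = list(value = iso$phase_C, units = "rad"),
      t_pisomax = list(value = iso$t_pisomax, units = "s"),
      rms_residual = list(value = iso$rms_residual, units = "mmHg"),
      suspect = iso$suspect),
    triangular_flow = list(
      t_onset = tri$t_onset, t_peak = tri$t_peak, t_end = tri$t_end,
      q_peak = list(value = tri$q_peak, units = "mL/s"),
      SV = list(value = tri$SV, units = "mL")),
    results = lapply(analysis$results, one_source))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @export
print.lv_analysis <- function(x, ...) {
  cat("<lv_analysis>\n")
  print(x$iso)
  print(x$triangle)
  for (nm in names(x$results)) {
    cat(sprintf("-- %s --\n", nm))
    print(x$results[[nm]]$es)
    print(x$results[[nm]]$er)
  }
  invisible(x)
}
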