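# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Normalised time-varying elastance shape on [0, T): double-Hill activation
# (rise Hill times decay Hill), scaled to peak 1.  The shape constants give
# peak elastance near one third of the cycle, a realistic systolic fraction.
.elastance_shape_cache <- new.env(parent = emptyenv())

.elastance_shape <- function(tfrac, m1 = 1.32, m2 = 27.4,
                             tau1 = 0.269, tau2 = 0.452) {
  raw <- function(tf) {
    h1 <- (tf / tau1)^m1
    (h1 / (1 + h1)) / (1 + (tf / tau2)^m2)
  }
  key <- paste(m1, m2, tau1, tau2)
  peak <- .elastance_shape_cache[[key]]
  if (is.null(peak)) {
    peak <- max(raw(seq(0, 1, length.out = 2001)))
    .elastance_shape_cache[[key]] <- peak
  }
  raw(tfrac) / peak
}

#' Simulation parameter presets
#'
#' Parameter bundles for the mechanistic beat simulator, tuned so that the
#' `NC` preset reproduces rat-scale healthy hemodynamics (heart rate about
#' 398 beats/min, cardiac output about 2.26 mL/s, peak isovolumic pressure
#' about 263 mmHg) and the disease-like presets are caricatures of chronic
#' kidney disease (lower elastance, larger effective volume) and type 1 /
#' type 2 diabetes (lower elastance and, for type 2, lower maximum flow and
#' output).  They are testing fixtures, not biological claims.
#'
#' @param preset one of `"NC"`, `"CKD"`, `"T1DM"`, `"T2DM"`.
#' @param ... overrides of individual fields (e.g. `HR`, `E_max_true`,
#'   `noise_sd_pct`, `seed`).
#' @return A named list of class `lv_simparams`: `HR` (beats/min),
#'   `E_max_true` and `E_min` (mmHg/mL), `Q_max_true` (mL/s, zero-load flow
#'   of the ventricle's internal resistance), `V0` (mL, dead volume),
#'   windkessel `Rc`, `Rp` (mmHg s/mL) and `Ca` (mL/mmHg), venous filling
#'   `P_ven` (mmHg) and `R_mv` (mmHg s/mL), `noise_sd_pct` (% of peak
#'   pressure) and `seed`.
#' @export
sim_params <- function(preset = c("NC", "CKD", "T1DM", "T2DM"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    NC   = list(HR = 398.0, E_max_true = 450, E_min = 9,  V0 = 0.03,
                Q_max_true = 38, Rc = 1.5, Rp = 36.0, Ca = 0.0045,
                P_ven = 9.00, R_mv = 1.10),
    CKD  = list(HR = 385.2, E_max_true = 380, E_min = 8,  V0 = 0.03,
                Q_max_true = 42, Rc = 1.3, Rp = 50.0, Ca = 0.0050,
                P_ven = 9.60, R_mv = 1.05),
    T1DM = list(HR = 342.7, E_max_true = 370, E_min = 8,  V0 = 0.03,
                Q_max_true = 33, Rc = 1.5, Rp = 34.0, Ca = 0.0048,
                P_ven = 8.85, R_mv = 0.95),
    T2DM = list(HR = 384.5, E_max_true = 330, E_min = 8,  V0 = 0.03,
                Q_max_true = 24, Rc = 2.0, Rp = 50.0, Ca = 0.0045,
                P_ven = 8.80, R_mv = 1.05))
  p <- utils::modifyList(c(base, list(noise_sd_pct = 1, seed = 1L,
                                      preset = preset)),
                         list(...))
  num <- p[setdiff(names(p), c("preset", "seed", "noise_sd_pct"))]
  if (any(!vapply(num, function(x) is.numeric(x) && x > 0, TRUE)))
    stop("all physical simulation parameters must be positive")
  if (p$noise_sd_pct < 0) stop("noise_sd_pct must be >= 0")
  structure(p, class = "lv_simparams")
}

#' Simulate one steady-state ejecting beat (mechanistic model)
#'
#' Integrates an elastance-resistance ventricle coupled to a three-element
#' windkessel with a diode aortic valve.  The ventricular source follows
#' the series elastance-resistance formulation: the chamber pressure is
#' `P_lv = E(t) (V - V0) - R_v(t) Q` with the internal resistance
#' proportional to the isovolumic pressure of the beat,
#' `R_v(t) = P_iso(t) / Q_max_true` where `P_iso(t) = E(t) (V_ed - V0)`.
#' With ejected volume `V_ej = V_ed - V` this is algebraically identical to
#' `P_lv = P_iso(t) (1 - V_ej/V_eed - Q/Q_max)` with `V_eed = V_ed - V0` —
#' the ejecting beat carries exact elastance-resistance ground truth while
#' the load (windkessel), valve timing and filling emerge mechanistically.
#' Aortic flow follows from pressure balance across the characteristic
#' resistance, `P_lv = P_a + Q Rc` while the valve is open; windkessel
#' `Ca dP_a/dt = Q - P_a / Rp`; constant-pressure venous filling through
#' `R_mv` in diastole.
#' Fixed-step 4th-order Runge-Kutta at 0.5 ms is run to periodic steady
#' state (volume and arterial pressure repeat to 1e-6 relative; at most 50
#' beats) and the last beat is emitted at ~1 kHz.  An isovolumic twin (valve
#' disabled at the same end-diastolic volume) provides the true peak
#' isovolumic pressure.  Seeded Gaussian noise (SD = `noise_sd_pct`% of peak
#' pressure) is added to the emitted pressure channel only.
#'
#' @param params an `lv_simparams` from [sim_params()].
#' @param valve open the aortic valve normally (default); `FALSE` clamps
#'   aortic flow to zero, producing the isovolumic twin beat.
#' @return An object of class `lv_synthbeat`: `beat` (an [lv_beat], noisy
#'   pressure), `flow` (an [lv_trace], mL/s), `CO` (mL/s), `HR`, `truth`
#'   (list: `P_isomax_true`, `E_max_true`, `V_ed`, `V0`, `SV`, `t_ej_true`,
#'   `t_ee_true`, `params`), and `clean` (noise-free pressure trace),
#'   `volume` (LV volume trace, mL).
#' @export
simulate_beat_modeA <- function(params, valve = TRUE) {
  stopifnot(inherits(params, "lv_simparams"))
  T <- 60 / params$HR
  nsteps <- 2L * max(4L, round(T / 1e-3))     # ~0.5 ms internal step
  h <- T / nsteps
  E_of <- function(t) {
    tf <- (t %% T) / T
    params$E_min + (params$E_max_true - params$E_min) * .elastance_shape(tf)
  }
  # state y = (V, Pa, S_ej, S_in); S are RK4-consistent flow integrals.
  # v_ed is the volume at the start of the current beat, which sets the
  # beat's isovolumic pressure curve and hence the internal resistance.
  deriv <- function(t, y, v_ed) {
    E <- E_of(t)
    p0 <- E * (y[1] - params$V0)
    piso <- E * (v_ed - params$V0)
    q <- if (!valve) 0 else
      max(0, (p0 - y[2]) / (params$Rc + piso / params$Q_max_true))
    plv <- p0 - piso * q / params$Q_max_true
    qin <- max(0, (params$P_ven - plv) / params$R_mv)
    c(qin - q, (q - y[2] / params$Rp) / params$Ca, q, qin)
  }
  rk4_beat <- function(y, record = FALSE) {
    if (record) hist <- matrix(NA_real_, nsteps + 1L, 4L)
    if (record) hist[1L, ] <- y
    v_ed <- y[1L]
    t <- 0
    for (i in seq_len(nsteps)) {
      k1 <- deriv(t, y, v_ed)
      k2 <- deriv(t + h / 2, y + h / 2 * k1, v_ed)
      k3 <- deriv(t + h / 2, y + h / 2 * k2, v_ed)
      k4 <- deriv(t + h, y + h * k3, v_ed)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
      if (record) hist[i + 1L, ] <- y
    }
    if (record) list(y = y, hist = hist) else list(y = y)
  }

  y <- c(params$V0 + 0.5, 80, 0, 0)
  prev <- y[1:2]
  converged <- FALSE
  for (b in seq_len(50L)) {
    y <- rk4_beat(y)$y
    if (all(abs(y[1:2] - prev) <= 1e-6 * pmax(abs(prev), 1))) {
      converged <- TRUE
      break
    }
    prev <- y[1:2]
  }
  if (!converged) stop("simulation did not reach periodic steady state")

  res <- rk4_beat(y, record = TRUE)
  hist <- res$hist
  keep <- seq(1L, nsteps, by = 2L)            # emit at ~1 kHz
  dt <- 2 * h
  tt <- (keep - 1L) * h
  V <- hist[keep, 1L]; Pa <- hist[keep, 2L]
  V_ed0 <- hist[1L, 1L]
  Et <- params$E_min +
    (params$E_max_true - params$E_min) * .elastance_shape(tt / T)
  p0 <- Et * (V - params$V0)
  piso_t <- Et * (V_ed0 - params$V0)
  q <- if (!valve) rep(0, length(keep)) else
    pmax(0, (p0 - Pa) / (params$Rc + piso_t / params$Q_max_true))
  p_lv <- p0 - piso_t * q / params$Q_max_true

  V_ed <- V_ed0
  SV <- hist[nsteps + 1L, 3L] - hist[1L, 3L]  # RK4-consistent ejected volume
  CO <- SV * params$HR / 60
  if (valve) {
    ej <- range(which(q > 0))
    if (!is.finite(ej[1L])) stop("no ejection in simulated beat")
  } else {
    ej <- c(NA_integer_, NA_integer_)
  }

  p_noisy <- p_lv
  if (params$noise_sd_pct > 0) {
    p_noisy <- with_seed(params$seed, {
      p_lv + stats::rnorm(length(p_lv),
                          sd = params$noise_sd_pct / 100 * max(p_lv))
    })
  }
  beat <- pressure_beat(lv_trace(p_noisy, dt = dt, t0 = 0, units = "mmHg",
                                 label = "p_lv"), T = length(keep) * dt)
  structure(
    list(beat = beat,
         flow = lv_trace(q, dt = dt, t0 = 0, units = "mL/s", label = "q_ao"),
         clean = lv_trace(p_lv, dt = dt, t0 = 0, units = "mmHg",
                          label = "p_lv_clean"),
         volume = lv_trace(V, dt = dt, t0 = 0, units = "mL", label = "v_lv"),
         aortic = lv_trace(Pa + q * params$Rc, dt = dt, t0 = 0,
                           units = "mmHg", label = "p_ao"),
         CO = CO, HR = params$HR,
         truth = list(P_isomax_true = params$E_max_true * (V_ed - params$V0),
                      E_max_true = params$E_max_true,
                      Q_max_true = params$Q_max_true,
                      V_ed = V_ed, V0 = params$V0, SV = SV,
                      t_ej_true = if (valve) tt[ej[1L]] else NA_real_,
                      t_ee_true = if (valve) tt[ej[2L]] else NA_real_,
                      params = params)),
    class = "lv_synthbeat")
}

#' Compose a model-consistent beat (exact ground truth)
#'
#' Builds a beat directly from the elastance-resistance equation: a
#' shifted-cosine isovolumic pressure, a triangular aortic flow on a stated
#' ejection window, and the composed ejecting pressure
#' `P_iso (1 - V_ej/V_eed - Q/Q_max)` inside the window (the isovolumic
#' curve elsewhere).  Because the construction uses the model itself, the
#' true `Q_max` and `V_eed` are exact by composition, which makes this the
#' recovery fixture for the fitting stages.
#'
#' @param HR heart rate, beats/min.
#' @param P_d end-diastolic pressure, mmHg.
#' @param P_idmax peak developed isovolumic pressure, mmHg
#'   (`P_isomax = P_d + P_idmax`).
#' @param V_eed_true effective end-diastolic volume, mL (must exceed SV).
#' @param Q_max_true theoretical maximum flow, mL/s (must exceed the
#'   triangle's peak flow).
#' @param CO cardiac output, mL/s.
#' @param t_lead diastolic lead-in before contraction onset, s.
#' @param t_rise_frac time from contraction onset to the isovolumic peak, as
#'   a fraction of the period.
#' @param ej_on_frac ejection onset as a fraction of the rise time.
#' @param ej_end_frac ejection end as a fraction of the rise time.
#' @param apex_frac position of the flow peak within the ejection window.
#' @param fs sampling rate, Hz.
#' @param noise_sd_pct,seed optional pressure noise as in
#'   [simulate_beat_modeA()].
#' @return An `lv_synthbeat`; `truth` carries the exact `Q_max_true`,
#'   `V_eed_true`, `P_isomax_true` and the landmark times, and `beat` has
#'   its landmarks set to the true values.
#' @export
compose_beat_modeB <- function(HR = 398, P_d = 5, P_idmax = 258,
                               V_eed_true = 0.60, Q_max_true = 30,
                               CO = 2.26, t_lead = 0.01, t_rise_frac = 0.35,
                               ej_on_frac = 0.30, ej_end_frac = 1.60,
                               apex_frac = 0.22, fs = 1000,
                               noise_sd_pct = 0, seed = 1L) {
  stopifnot(HR > 0, P_idmax > 0, V_eed_true > 0, Q_max_true > 0, CO > 0)
  T <- 60 / HR
  N <- round(T * fs)
  dt <- T / N
  tt <- (seq_len(N) - 1L) * dt
  snap <- function(t) .snap_to_grid(t, 0, dt, N)

  t_rise <- t_rise_frac * T
  omega <- pi / t_rise
  t_ed <- snap(t_lead)
  t_ej <- snap(t_ed + ej_on_frac * t_rise)
  t_ee <- snap(t_ed + ej_end_frac * t_rise)
  if (t_ee >= T) stop("ejection window exceeds the beat period")
  SV <- CO * 60 / HR
  if (V_eed_true <= SV) stop("V_eed_true must exceed the stroke volume")

  piso <- rep(P_d, N)
  act <- tt >= t_ed & tt <= t_ed + 2 * pi / omega
  piso[act] <- P_d + (P_idmax / 2) * (1 - cos(omega * (tt[act] - t_ed)))

  tri <- calibrate_triangle(
    c(t_onset = t_ej, t_peak = snap(t_ej + apex_frac * (t_ee - t_ej)),
      t_end = t_ee),
    CO = CO, HR = HR,
    grid = lv_trace(numeric(N), dt = dt, t0 = 0, units = "mL/s",
                    label = "grid"))
  if (Q_max_true <= tri$q_peak)
    stop("Q_max_true must exceed the triangular peak flow (",
         signif(tri$q_peak, 4), " mL/s)")
  q <- tri$samples$values
  vej <- as.numeric(pracma::cumtrapz(tt, q))

  # half-open window: at t_ee the ejected-volume term would make the
  # composed pressure jump below the isovolumic curve used from t_ee on,
  # and the boundary sample belongs to the relaxation limb
  p <- piso
  win <- tt >= t_ej & tt < t_ee
  p[win] <- piso[win] * (1 - vej[win] / V_eed_true - q[win] / Q_max_true)
  if (any(p[win] <= 0))
    stop("composed pressure is non-positive on the ejection window; ",
         "parameters are inconsistent")

  p_noisy <- p
  if (noise_sd_pct > 0)
    p_noisy <- with_seed(seed,
      p + stats::rnorm(N, sd = noise_sd_pct / 100 * max(p)))
  beat <- pressure_beat(lv_trace(p_noisy, dt = dt, t0 = 0, units = "mmHg",
                                 label = "p_lv"),
                        T = T, t_ed = t_ed, t_ej = t_ej, t_ee = t_ee)
  structure(
    list(beat = beat, flow = tri$samples,
         clean = lv_trace(p, dt = dt, t0 = 0, units = "mmHg",
                          label = "p_lv_clean"),
         CO = CO, HR = HR,
         truth = list(P_isomax_true = P_d + P_idmax, P_d = P_d,
                      P_idmax = P_idmax, omega = omega,
                      E_max_true = (P_d + P_idmax) / V_eed_true,
                      Q_max_true = Q_max_true, V_eed_true = V_eed_true,
                      SV = SV, t_ed = t_ed, t_ej_true = t_ej,
                      t_ee_true = t_ee,
                      t_pisomax_true = t_ed + t_rise)),
    class = "lv_synthbeat")
}

#' @export
print.lv_synthbeat <- function(x, ...) {
  cat(sprintf("<lv_synthbeat> HR = %.4g /min, CO = %.4g mL/s, P_isomax_true = %.4g mmHg\n",
              x$HR, x$CO, x$truth$P_isomax_true))
  invisible(x)
}

#' Generate a synthetic cohort with a truth manifest
#'
#' Draws `n` beats from the mechanistic simulator with preset membership
#' sampled by `preset_mix` and mild log-normal between-animal variation of
#' contractility, afterload and filling, all driven by one seeded
#' generator.  Optionally writes one CSV record per beat plus a `truth.csv`
#' manifest.
#'
#' @param n cohort size.
#' @param preset_mix named weights over `c(NC, CKD, T1DM, T2DM)`.
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @param noise_sd_pct pressure noise level passed to each simulation.
#' @param out_dir optional directory for CSV records and `truth.csv`.
#' @return List with `beats` (list of `lv_synthbeat`) and `manifest`
#'   (data frame: id, preset, HR, CO, SV, P_isomax_true, E_max_true, V_ed).
#' @export
generate_cohort <- function(n, preset_mix = c(NC = 25, CKD = 14,
                                              T1DM = 20, T2DM = 12),
                            seed = 1L, noise_sd_pct = 1, out_dir = NULL) {
  stopifnot(n >= 1, all(preset_mix >= 0), sum(preset_mix) > 0)
  draws <- with_seed(seed, {
    list(preset = sample(names(preset_mix), n, replace = TRUE,
                         prob = preset_mix / sum(preset_mix)),
         jit = matrix(stats::rnorm(5L * n), ncol = 5L),
         seeds = sample.int(2147483646L, n))
  })
  beats <- vector("list", n)
  for (i in seq_len(n)) {
    base <- sim_params(draws$preset[i])
    # between-animal dispersion calibrated to the reported cohort spread
    # (E_max interquartile range near a quarter of its median)
    p <- sim_params(draws$preset[i],
                    E_max_true = base$E_max_true * exp(0.185 * draws$jit[i, 1]),
                    Rp = base$Rp * exp(0.12 * draws$jit[i, 2]),
                    P_ven = base$P_ven * exp(0.08 * draws$jit[i, 3]),
                    HR = base$HR * exp(0.04 * draws$jit[i, 4]),
                    Q_max_true = base$Q_max_true * exp(0.18 * draws$jit[i, 5]),
                    noise_sd_pct = noise_sd_pct, seed = draws$seeds[i])
    beats[[i]] <- simulate_beat_modeA(p)
  }
  manifest <- data.frame(
    id = sprintf("rec%03d", seq_len(n)),
    preset = draws$preset,
    HR = vapply(beats, function(b) b$HR, 0),
    CO = vapply(beats, function(b) b$CO, 0),
    SV = vapply(beats, function(b) b$truth$SV, 0),
    P_isomax_true = vapply(beats, function(b) b$truth$P_isomax_true, 0),
    E_max_true = vapply(beats, function(b) b$truth$E_max_true, 0),
    Q_max_true = vapply(beats, function(b) b$truth$Q_max_true, 0),
    V_ed = vapply(beats, function(b) b$truth$V_ed, 0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n))
      write_record(list(p_lv_mmHg = beats[[i]]$beat$pressure,
                        q_ao_ml_s = beats[[i]]$flow),
                   file.path(out_dir, paste0(manifest$id[i], ".csv")))
    utils::write.csv(manifest, file.path(out_dir, "truth.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(beats = beats, manifest = manifest)
}

#' Write a multi-beat record (with ECG) from a simulated beat
#'
#' Tiles the emitted steady-state beat `n_beats` times, regenerating the
#' pressure noise independently per beat, and adds a synthetic ECG channel
#' with an R-wave spike at each beat onset, producing a record suitable for
#' the beat-selection and ensemble-averaging path of [analyze_record()].
#'
#' @param sb an `lv_synthbeat` from [simulate_beat_modeA()].
#' @param n_beats number of beats to tile.
#' @param path output CSV path.
#' @param seed seed for the per-beat noise.
#' @return `path`, invisibly.
#' @export
synthetic_record <- function(sb, n_beats = 5L, path, seed = 1L) {
  stopifnot(inherits(sb, "lv_synthbeat"), n_beats >= 1L)
  clean <- sb$clean$values
  n <- length(clean)
  dt <- sb$clean$dt
  sdp <- sb$truth$params$noise_sd_pct / 100 * max(clean)
  p <- with_seed(seed,
    rep(clean, n_beats) + stats::rnorm(n * n_beats, sd = sdp))
  q <- rep(sb$flow$values, n_beats)
  tt <- (seq_len(n * n_beats) - 1L) * dt
  ecg <- numeric(n * n_beats)
  for (b in seq_len(n_beats)) {
    i0 <- (b - 1L) * n
    spike <- exp(-((seq_len(n) - 3L) * dt / 0.004)^2)
    ecg[i0 + seq_len(n)] <- spike
  }
  write_record(list(p_lv_mmHg = lv_trace(p, dt = dt, units = "mmHg",
                                         label = "p_lv"),
                    q_ao_ml_s = lv_trace(q, dt = dt, units = "mL/s",
                                         label = "q_ao"),
                    ecg_mv = lv_trace(ecg, dt = dt, units = "mV",
                                      label = "ecg")),
               path)
}
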