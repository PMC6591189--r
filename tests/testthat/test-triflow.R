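test_that("the filtered fourth derivative of a pure tone rings at T/(2k)", {
  n <- 160; T <- 0.16; k <- 3
  tt <- (seq_len(n) - 1) * T / n
  p <- 100 + 20 * cos(2 * pi * k * tt / T)
  FF <- fourier_truncate(derivative4(p, T), 15)
  zc <- lvpump:::.zero_crossings(FF, tt)
  expect_equal(diff(zc$t), rep(T / (2 * k), nrow(zc) - 1), tolerance = 1e-3)
})

test_that("triangle landmarks recover a model-consistent ejection window", {
  sb <- quick_modeB()
  tri <- locate_triangle(sb$beat)
  # landmarks lie on the sample grid
  dt <- sb$beat$pressure$dt
  expect_equal(tri[["t_onset"]] / dt, round(tri[["t_onset"]] / dt),
               tolerance = 1e-9)
  expect_true(tri[["t_onset"]] < tri[["t_peak"]],
              tri[["t_peak"]] < tri[["t_end"]])
  # the detected window overlaps the true one substantially
  lo <- max(tri[["t_onset"]], sb$truth$t_ej_true)
  hi <- min(tri[["t_end"]], sb$truth$t_ee_true)
  un <- max(tri[["t_end"]], sb$truth$t_ee_true) -
    min(tri[["t_onset"]], sb$truth$t_ej_true)
  expect_gt((hi - lo) / un, 0.7)
})

test_that("calibrated triangle has area SV and peak 2 SV / base", {
  grid <- lv_trace(numeric(160), dt = 1e-3, units = "mL/s")
  # direct arithmetic: SV = 0.3 mL over a 0.06 s base
  tri <- calibrate_triangle(c(t_onset = 0.02, t_peak = 0.04, t_end = 0.08),
                            CO = 0.3 * 400 / 60, HR = 400, grid = grid)
  expect_equal(tri$q_peak, 10)
  expect_equal(tri$SV, 0.3)

  # healthy-rat numbers: CO and HR give SV = CO * 60 / HR
  tri2 <- calibrate_triangle(c(t_onset = 0.015, t_peak = 0.027, t_end = 0.075),
                             CO = 2.260, HR = 398, grid = grid)
  expect_equal(tri2$SV, 2.260 * 60 / 398)
  tt <- trace_times(tri2$samples)
  expect_equal(pracma::trapz(tt, tri2$samples$values), tri2$SV,
               tolerance = 1e-6 * tri2$SV)
  expect_equal(tri2$q_peak, 2 * tri2$SV / (tri2$t_end - tri2$t_onset))

  # area does not depend on where the apex sits
  tri3 <- calibrate_triangle(c(t_onset = 0.02, t_peak = 0.032, t_end = 0.08),
                             CO = 0.3 * 400 / 60, HR = 400, grid = grid)
  expect_equal(pracma::trapz(tt, tri3$samples$values), 0.3,
               tolerance = 1e-6 * 0.3)
  expect_equal(tri3$q_peak, tri$q_peak)

  expect_error(calibrate_triangle(c(t_onset = 0.02, t_peak = 0.021,
                                    t_end = 0.022),
                                  CO = 2, HR = 400, grid = grid),
               "degenerate")
})

test_that("doubling cardiac output doubles the peak flow exactly", {
  grid <- lv_trace(numeric(160), dt = 1e-3, units = "mL/s")
  times <- c(t_onset = 0.02, t_peak = 0.04, t_end = 0.08)
  t1 <- calibrate_triangle(times, CO = 1.1, HR = 380, grid = grid)
  t2 <- calibrate_triangle(times, CO = 2.2, HR = 380, grid = grid)
  expect_equal(t2$q_peak, 2 * t1$q_peak)
  expect_equal(t2$samples$values, 2 * t1$samples$values)
})

test_that("shifting the beat shifts the landmarks identically", {
  sb <- quick_modeB()
  p <- sb$beat$pressure$values
  k <- 6   # circular shift by 6 samples
  p2 <- c(p[(length(p) - k + 1):length(p)], p[1:(length(p) - k)])
  b2 <- pressure_beat(lv_trace(p2, dt = sb$beat$pressure$dt), T = sb$beat$T)
  tri1 <- locate_triangle(sb$beat)
  tri2 <- locate_triangle(b2)
  expect_equal(as.numeric(tri2) - as.numeric(tri1),
               rep(k * sb$beat$pressure$dt, 3), tolerance = 1e-9)
})

test_that("pipeline landmarks track the true ejection window on Mode-A beats", {
  presets <- rep(c("NC", "CKD", "T1DM", "T2DM"), each = 5)
  jac <- numeric(20); pk_err <- numeric(20)
  for (i in seq_along(presets)) {
    sb <- simulate_beat_modeA(sim_params(presets[i], noise_sd_pct = 1,
                                         seed = 100 + i))
    an <- analyze_beat(sb$beat, CO = sb$CO, HR = sb$HR)
    lo <- max(an$beat$t_ej, sb$truth$t_ej_true)
    hi <- min(an$beat$t_ee, sb$truth$t_ee_true)
    un <- max(an$beat$t_ee, sb$truth$t_ee_true) -
      min(an$beat$t_ej, sb$truth$t_ej_true)
    jac[i] <- (hi - lo) / un
    q <- sb$flow$values
    t_qpk <- (which.max(q) - 1) * sb$flow$dt
    ej_dur <- sb$truth$t_ee_true - sb$truth$t_ej_true
    pk_err[i] <- abs(an$triangle$t_peak - t_qpk) / ej_dur
  }
  expect_gte(sum(jac >= 0.8), 16)
  expect_lte(median(pk_err), 0.10)
})
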