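test_that("predicted pressure obeys the model's limiting cases", {
  piso <- c(50, 100, 200, 250)
  z <- rep(0, 4)
  expect_equal(predict_pressure(piso, z, z, Q_max = 30, V_eed = 0.6), piso)
  # at Q = Q_max with nothing ejected the load term cancels the pressure
  expect_equal(predict_pressure(piso, rep(30, 4), z, 30, 0.6), rep(0, 4))
  expect_error(predict_pressure(piso, z, z, -1, 0.6))
})

test_that("a composed beat is reproduced exactly at the true parameters", {
  sb <- quick_modeB()
  tt <- trace_times(sb$beat$pressure)
  piso <- sb$truth$P_d + (sb$truth$P_idmax / 2) *
    (1 - cos(sb$truth$omega * (tt - sb$truth$t_ed)))
  q <- sb$flow$values
  vej <- as.numeric(pracma::cumtrapz(tt, q))
  win <- tt >= sb$beat$t_ej & tt < sb$beat$t_ee
  pm <- predict_pressure(piso[win], q[win], vej[win],
                         sb$truth$Q_max_true, sb$truth$V_eed_true)
  expect_equal(pm, sb$beat$pressure$values[win], tolerance = 1e-12)
})

test_that("the fit recovers composed-beat parameters and its identities", {
  sb <- quick_modeB()
  an <- suppressWarnings(
    analyze_beat(sb$beat, CO = sb$CO, HR = sb$HR, flow = sb$flow))
  er <- an$results$mQ$er
  expect_equal(er$Q_max, sb$truth$Q_max_true, tolerance = 5e-3)
  expect_equal(er$V_eed, sb$truth$V_eed_true, tolerance = 5e-3)
  expect_equal(er$E_max * er$V_eed, er$P_isomax, tolerance = 1e-12)
  expect_equal(er$R_max * er$Q_max, er$P_isomax, tolerance = 1e-12)
  expect_gt(er$r2, 0.99)
  expect_gt(er$Q_max, max(sb$flow$values))
  expect_gt(er$V_eed, sb$truth$SV)
})

test_that("a coarse grid search brackets the optimiser's minimum", {
  sb <- quick_modeB()
  an <- suppressWarnings(
    analyze_beat(sb$beat, CO = sb$CO, HR = sb$HR, flow = sb$flow))
  er <- an$results$mQ$er
  sse_opt <- sum((er$fitted$p_meas - er$fitted$p_model)^2)

  tt <- trace_times(sb$beat$pressure)
  mask <- tt %in% er$fitted$t
  piso <- evaluate_piso(an$iso, er$fitted$t)
  q <- pmax(sb$flow$values[mask], 0)
  vej <- as.numeric(pracma::cumtrapz(tt, pmax(sb$flow$values, 0)))[mask]
  qs <- seq(1.05 * max(q), 50 * max(q), length.out = 50)
  vs <- seq(1.05 * sb$truth$SV, 20 * sb$truth$SV, length.out = 50)
  grid_min <- min(outer(qs, vs, Vectorize(function(qm, ve)
    sum((er$fitted$p_meas - predict_pressure(piso, q, vej, qm, ve))^2))))
  expect_lte(sse_opt, grid_min + 1e-9)
})

test_that("fitting is refused without ejection", {
  sb <- quick_modeB()
  zero_flow <- lv_trace(numeric(length(sb$flow$values)),
                        dt = sb$flow$dt, units = "mL/s")
  vol <- structure(list(times = c(sb$beat$t_ej, sb$beat$t_ee),
                        V_ej = c(0, 0), SV = 1e-9, n_clipped = 0L),
                   class = "lv_ejvol")
  iso <- suppressWarnings(
    fit_isovolumic(select_fit_segments(sb$beat),
                   P_d = sb$truth$P_d, t_ed = sb$beat$t_ed))
  expect_error(fit_er_model(sb$beat, iso, zero_flow, vol,
                            t_ej = sb$beat$t_ej),
               "unidentifiable")
})

test_that("analyze produces both result sets with flow, one without", {
  sb <- quick_modeB()
  both <- suppressWarnings(
    analyze_beat(sb$beat, CO = sb$CO, HR = sb$HR, flow = sb$flow))
  expect_named(both$results, c("triQ", "mQ"))
  expect_true(is.finite(both$results$mQ$er$E_max))
  expect_true(is.finite(both$results$triQ$er$Q_max))

  only <- suppressWarnings(analyze_beat(sb$beat, CO = sb$CO, HR = sb$HR))
  expect_named(only$results, "triQ")
})

test_that("analyze_record averages with ECG and runs single-beat without", {
  sb <- simulate_beat_modeA(sim_params("NC", noise_sd_pct = 1, seed = 5))
  multi <- withr::local_tempfile(fileext = ".csv")
  synthetic_record(sb, n_beats = 5, path = multi, seed = 9)
  an <- suppressWarnings(analyze_record(multi, CO = sb$CO, HR = sb$HR))
  expect_equal(an$selection$n_retained, 4)   # last beat has no closing R wave
  expect_named(an$results, c("triQ", "mQ"))

  single <- withr::local_tempfile(fileext = ".csv")
  write_record(list(p_lv_mmHg = sb$beat$pressure), single)
  an1 <- suppressWarnings(analyze_record(single, CO = sb$CO, HR = sb$HR))
  expect_null(an1$selection)
  expect_named(an1$results, "triQ")

  js <- result_json(an)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$schema_version, "1.0")
  expect_true(all(c("isovolumic", "triangular_flow", "results") %in%
                  names(parsed)))
  expect_equal(parsed$inputs$CO$units, "mL/s")
})
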