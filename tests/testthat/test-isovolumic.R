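# A beat whose pressure is exactly the shifted-cosine isovolumic curve,
# with a diastolic tail, for segment/fit tests.
sinusoid_beat <- function(P_d = 5, P_idmax = 245, omega = 2 * pi * 6.667,
                          t_ed = 0.01, T = 0.16, dt = 1e-3,
                          t_ej_frac = 0.25) {
  n <- round(T / dt)
  tt <- (seq_len(n) - 1) * dt
  p <- rep(P_d, n)
  act <- tt >= t_ed & tt <= t_ed + 2 * pi / omega
  p[act] <- P_d + (P_idmax / 2) * (1 - cos(omega * (tt[act] - t_ed)))
  t_rise <- pi / omega
  pressure_beat(lv_trace(p, dt = dt), T = n * dt, t_ed = t_ed,
                t_ej = t_ed + t_ej_frac * 2 * t_rise,
                t_ee = t_ed + 1.55 * t_rise)
}

test_that("fit segments come from the isovolumic parts of the beat", {
  b <- sinusoid_beat()
  segs <- select_fit_segments(b)
  expect_gte(nrow(segs$contraction), 10)   # 12+ ms of upstroke at 1 kHz
  expect_gt(nrow(segs$relaxation), 2)
  expect_true(all(segs$contraction$t >= b$t_ed & segs$contraction$t <= b$t_ej))
  expect_true(all(segs$relaxation$t >= b$t_ee))

  flat <- pressure_beat(lv_trace(rep(10, 160), dt = 1e-3), t_ed = 0.01,
                        t_ej = 0.03, t_ee = 0.08)
  expect_error(select_fit_segments(flat), "insufficient isovolumic samples")
})

test_that("exact model samples are recovered to high precision", {
  om <- 2 * pi * 6.667
  b <- sinusoid_beat(P_d = 5, P_idmax = 245, omega = om)
  segs <- select_fit_segments(b)
  fit <- fit_isovolumic(segs, P_d = 5, t_ed = b$t_ed)
  expect_equal(fit$P_idmax, 245, tolerance = 1e-6)
  expect_equal(fit$omega, om, tolerance = 1e-6)
  expect_equal(fit$phase_C, 0, tolerance = 1e-5)
  expect_equal(fit$P_isomax, 250, tolerance = 1e-6)
  expect_equal(fit$P_isomax, fit$P_d + fit$P_idmax)   # exact identity
  expect_lt(fit$rms_residual, 1e-6)
})

test_that("P_isomax is robust to moderate measurement noise", {
  om <- 2 * pi * 6.667
  b0 <- sinusoid_beat(P_d = 5, P_idmax = 245, omega = om)
  segs0 <- select_fit_segments(b0)
  set.seed(101)
  errs <- replicate(200, {
    segs <- lapply(segs0, function(d) {
      d$p <- d$p + rnorm(nrow(d), sd = 2)
      d
    })
    fit <- fit_isovolumic(segs, P_d = 5, t_ed = b0$t_ed)
    abs(fit$P_isomax - 250) / 250
  })
  expect_lt(median(errs), 0.05)
})

test_that("evaluate_piso reproduces the cosine and its maximum", {
  b <- sinusoid_beat()
  fit <- fit_isovolumic(select_fit_segments(b), P_d = 5, t_ed = b$t_ed)
  t_pk <- fit$t_ed + (pi - fit$phase_C) / fit$omega
  expect_equal(evaluate_piso(fit, t_pk), fit$P_d + fit$P_idmax,
               tolerance = 1e-9)
  t_zero <- fit$t_ed - fit$phase_C / fit$omega
  expect_equal(evaluate_piso(fit, t_zero), fit$P_d, tolerance = 1e-9)

  grid <- seq(fit$t_ed, fit$t_ed + 2 * pi / fit$omega, length.out = 1e5)
  vals <- evaluate_piso(fit, grid)
  expect_equal(max(vals), fit$P_isomax, tolerance = 1e-9 * fit$P_isomax)
  expect_lt(abs(grid[which.max(vals)] - fit$t_pisomax), diff(grid[1:2]) * 1.5)
})

test_that("the estimator is scale-equivariant and shift-invariant", {
  b <- sinusoid_beat()
  segs <- select_fit_segments(b)
  f1 <- fit_isovolumic(segs, P_d = 5, t_ed = b$t_ed)

  segs_scaled <- lapply(segs, function(d) { d$p <- 3 * d$p; d })
  f3 <- fit_isovolumic(segs_scaled, P_d = 15, t_ed = b$t_ed)
  expect_equal(f3$P_idmax, 3 * f1$P_idmax, tolerance = 1e-6)
  expect_equal(f3$P_isomax, 3 * f1$P_isomax, tolerance = 1e-6)

  shift <- 0.005
  segs_shift <- lapply(segs, function(d) { d$t <- d$t + shift; d })
  fs <- fit_isovolumic(segs_shift, P_d = 5, t_ed = b$t_ed + shift)
  expect_equal(fs$P_isomax, f1$P_isomax, tolerance = 1e-6)
  expect_equal(fs$t_pisomax - shift, f1$t_pisomax, tolerance = 1e-6)
})

test_that("an implausibly low fitted peak is flagged as suspect", {
  # a steep contraction to high pressure with a low relaxation tail makes
  # the least-squares sinusoid peak below the largest measured sample,
  # which is physically impossible for a true isovolumic curve
  tc <- seq(0, 0.02, by = 1e-3); tr <- seq(0.03, 0.042, by = 1e-3)
  segs <- list(contraction = data.frame(t = tc, p = 5 + 215 * (tc / 0.02)^1.5),
               relaxation = data.frame(t = tr, p = 70 - 2000 * (tr - 0.03)))
  expect_warning(fit <- fit_isovolumic(segs, P_d = 5, t_ed = 0),
                 "below the largest")
  expect_true(fit$suspect)
})
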