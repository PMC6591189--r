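test_that("trace construction validates its invariants", {
  expect_error(lv_trace(1:4, dt = 0.001), "at least 8")
  expect_error(lv_trace(c(1:7, NA), dt = 0.001), "finite")
  expect_error(lv_trace(1:10, dt = 0), "positive")
  tr <- lv_trace(sin(1:100), dt = 0.002, t0 = 0.5)
  expect_equal(trace_times(tr)[1], 0.5)
  expect_equal(diff(trace_times(tr))[1], 0.002)
})

test_that("CSV records round-trip and reject malformed grids", {
  tt <- (0:199) / 1000
  p <- 80 + 30 * sin(2 * pi * 5 * tt)
  e <- exp(-((tt - 0.05) / 0.004)^2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_record(list(p_lv_mmHg = lv_trace(p, dt = 1e-3),
                    ecg_mv = lv_trace(e, dt = 1e-3)), path)
  traces <- read_record(path)
  expect_named(traces, c("p_lv", "ecg"))
  expect_equal(traces$p_lv$dt, 1e-3, tolerance = 1e-12)
  expect_equal(traces$p_lv$values, p, tolerance = 1e-12)
  expect_equal(traces$ecg$values, e, tolerance = 1e-12)

  # duplicated timestamp makes the grid non-uniform
  bad <- read.csv(path)
  bad$time_s[10] <- bad$time_s[9]
  bad_path <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, bad_path, row.names = FALSE)
  expect_error(read_record(bad_path), "non-")

  expect_error(read_record(path, column_map = c(x = "nope")), "missing column")
})

test_that("beat selection excludes RR outliers and averages noise down", {
  # one smooth template beat, tiled with an RR outlier
  T0 <- 0.15
  beat_of <- function(t) 80 + 40 * sin(2 * pi * t / T0)^2
  dt <- 1e-3
  rr <- c(0.15, 0.15, 0.161, 0.15, 0.15)   # third beat ~6% above the mean RR
  fid <- cumsum(c(0.002, rr))
  tt <- seq(0, sum(rr) + 0.01, by = dt)
  p <- beat_of(tt)   # periodic enough for the retained beats
  sel <- select_and_average_beats(lv_trace(p, dt = dt), fid)
  expect_equal(sel$report$n_input, 5)
  expect_equal(sel$report$n_retained, 4)
  expect_equal(sel$report$excluded$index, 3)

  # identical beats: average equals any single beat
  fid2 <- 0.002 + (0:4) * T0
  sel2 <- select_and_average_beats(lv_trace(p, dt = dt), fid2)
  one <- approx(tt, p, xout = fid2[1] + (seq_along(sel2$beat$pressure$values) - 1) * dt)$y
  expect_equal(sel2$beat$pressure$values, one, tolerance = 1e-12)

  expect_error(select_and_average_beats(lv_trace(p, dt = dt), fid[1]),
               "complete RR")
})

test_that("averaging N noisy copies shrinks noise like 1/sqrt(N)", {
  T0 <- 0.15; dt <- 1e-3; N <- 9; sigma <- 2
  tt <- seq(0, (N + 0.5) * T0, by = dt)
  template <- 80 + 40 * sin(2 * pi * tt / T0)^2
  fid <- (0:(N)) * T0
  set.seed(7)
  resid_sd <- replicate(50, {
    noisy <- template + rnorm(length(template), sd = sigma)
    sel <- select_and_average_beats(lv_trace(noisy, dt = dt), fid)
    grid <- (seq_along(sel$beat$pressure$values) - 1) * dt
    sd(sel$beat$pressure$values - (80 + 40 * sin(2 * pi * grid / T0)^2))
  })
  expect_equal(mean(resid_sd), sigma / sqrt(N), tolerance = 0.2)
})

test_that("fourier_truncate keeps low harmonics and zeroes the rest", {
  n <- 64; t <- (0:(n - 1)) / n
  x <- 5 + cos(2 * pi * 3 * t)
  expect_equal(fourier_truncate(x, 15), x, tolerance = 1e-9)
  hi <- cos(2 * pi * 20 * t)
  expect_equal(fourier_truncate(hi, 15), rep(0, n), tolerance = 1e-9)
  expect_error(fourier_truncate(x, 32), "truncate")
  expect_error(fourier_truncate(x[1:4], 1), "8 samples")
})

test_that("fourier_truncate matches the double-loop DFT oracle", {
  set.seed(11)
  x <- rnorm(48)
  expect_equal(fourier_truncate(x, 15), dft_truncate_oracle(x, 15),
               tolerance = 1e-9)
})

test_that("fourier_truncate is idempotent and never gains energy", {
  set.seed(3)
  for (rep in 1:5) {
    x <- rnorm(100)
    y <- fourier_truncate(x, 15)
    expect_equal(fourier_truncate(y, 15), y, tolerance = 1e-12)
    expect_lte(sum(y^2), sum(x^2) + 1e-9)
  }
})

test_that("derivative4 acts as the spectral fourth derivative", {
  n <- 128; T <- 0.5; t <- (0:(n - 1)) * T / n
  x <- cos(2 * pi * t / T)
  expect_equal(derivative4(x, T), (2 * pi / T)^4 * x,
               tolerance = 1e-9 * (2 * pi / T)^4)
  expect_equal(derivative4(rep(3, n), T), rep(0, n))
  expect_error(derivative4(1:4, 1), "8 samples")
})

test_that("derivative4 matches the repeated finite-difference oracle", {
  sig <- band_limited_signal(n = 512, T = 1, k = 5, seed = 2)
  d4 <- derivative4(sig$x, sig$T)
  fd <- fd_derivative_oracle(sig$x, sig$T, order = 4)
  expect_lt(sqrt(mean((d4 - fd)^2)) / sqrt(mean(d4^2)), 1e-6)
})

test_that("derivative4 commutes with fourier_truncate", {
  set.seed(5)
  x <- rnorm(120); T <- 0.2
  a <- derivative4(fourier_truncate(x, 15), T)
  b <- fourier_truncate(derivative4(x, T), 15)
  expect_equal(a, b, tolerance = 1e-9)
})
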