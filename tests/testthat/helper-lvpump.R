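# Shared fixtures, all generated in code.

# One period of a band-limited signal: DC plus the first `k` harmonics with
# fixed coefficients drawn from a seeded generator.
band_limited_signal <- function(n = 256, T = 1, k = 5, seed = 1) {
  set.seed(seed)
  a <- stats::rnorm(k); b <- stats::rnorm(k)
  t <- (seq_len(n) - 1) * T / n
  x <- rep(stats::rnorm(1), n)
  for (j in seq_len(k))
    x <- x + a[j] * cos(2 * pi * j * t / T) + b[j] * sin(2 * pi * j * t / T)
  list(t = t, x = x, T = T)
}

# Brute-force DFT double loop (the independent oracle for fourier_truncate).
dft_truncate_oracle <- function(x, n_harmonics) {
  n <- length(x)
  X <- complex(n)
  for (k in 0:(n - 1)) {
    s <- 0i
    for (j in 0:(n - 1)) s <- s + x[j + 1] * exp(-2i * pi * k * j / n)
    X[k + 1] <- s
  }
  keep <- pmin(0:(n - 1), n - (0:(n - 1))) <= n_harmonics
  X[!keep] <- 0
  out <- numeric(n)
  for (j in 0:(n - 1)) {
    s <- 0i
    for (k in 0:(n - 1)) s <- s + X[k + 1] * exp(2i * pi * k * j / n)
    out[j + 1] <- Re(s) / n
  }
  out
}

# 5-point central first difference with periodic wrap, applied `order` times
# (the finite-difference oracle for the spectral derivative).
fd_derivative_oracle <- function(x, T, order = 4) {
  n <- length(x)
  h <- T / n
  for (o in seq_len(order)) {
    xp1 <- x[c(2:n, 1)]; xp2 <- x[c(3:n, 1:2)]
    xm1 <- x[c(n, 1:(n - 1))]; xm2 <- x[c(n - 1, n, 1:(n - 2))]
    x <- (xm2 - 8 * xm1 + 8 * xp1 - xp2) / (12 * h)
  }
  x
}

# A quick model-consistent beat for pipeline tests.
quick_modeB <- function(seed = 1, noise_sd_pct = 0, ...) {
  compose_beat_modeB(HR = 380, P_d = 5, P_idmax = 255, V_eed_true = 0.65,
                     Q_max_true = 30, CO = 2.0, noise_sd_pct = noise_sd_pct,
                     seed = seed, ...)
}

# Draw admissible Mode-B parameters in the stated physiological ranges,
# keeping SV below V_eed and the triangular peak below Q_max.
draw_modeB_params <- function() {
  P_isomax <- stats::runif(1, 190, 285)
  P_d <- stats::runif(1, 4, 8)
  V_eed <- stats::runif(1, 0.4, 1.0)
  Q_max <- stats::runif(1, 10, 40)
  HR <- stats::runif(1, 340, 400)
  SV <- min(0.55 * V_eed, 0.35 * Q_max * 60 / HR * 0.5)
  list(HR = HR, P_d = P_d, P_idmax = P_isomax - P_d, V_eed_true = V_eed,
       Q_max_true = Q_max, CO = SV * HR / 60)
}
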