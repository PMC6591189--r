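#' Truncate a periodic signal to its first harmonics
#'
#' Treats the input as one full period, computes its discrete Fourier
#' transform, keeps the mean (harmonic 0) and harmonics `1..n_harmonics`,
#' zeroes everything above, and returns the real inverse transform.  This is
#' the low-pass step used throughout: the triangular-flow landmarks are read
#' from the first 15 harmonics of the fourth pressure derivative.
#'
#' @param x numeric vector, one full period of samples.
#' @param n_harmonics number of harmonics to keep (default 15).
#' @return Numeric vector of the same length, band-limited to
#'   `n_harmonics` harmonics.
#' @export
#' @examples
#' t <- seq(0, 1, length.out = 64)[-64]
#' x <- 5 + cos(2 * pi * 3 * t)
#' max(abs(fourier_truncate(x, 15) - x)) < 1e-9
fourier_truncate <- function(x, n_harmonics = 15L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) stop("need at least 8 samples")
  n_harmonics <- as.integer(n_harmonics)
  if (n_harmonics < 1L) stop("n_harmonics must be >= 1")
  if (n_harmonics >= n / 2)
    stop("n_harmonics = ", n_harmonics, " leaves nothing to truncate for n = ",
         n, " samples")
  X <- stats::fft(x)
  k <- c(0:(n - 1L))
  freq <- pmin(k, n - k)           # harmonic number of each DFT bin
  X[freq > n_harmonics] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Spectral derivative of integer order on one period: harmonic k (signed
# frequency m) is multiplied by (i*2*pi*m/T)^order.  For odd orders the
# Nyquist bin (even n) is zeroed, the usual convention for a real result.
spectral_derivative <- function(x, T, order = 1L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) stop("need at least 8 samples")
  stopifnot(T > 0)
  k <- 0:(n - 1L)
  m <- ifelse(k <= n / 2, k, k - n)          # signed frequency index
  mult <- (1i * 2 * pi * m / T)^order
  if (order %% 2L == 1L && n %% 2L == 0L) mult[n / 2 + 1L] <- 0
  Re(stats::fft(stats::fft(x) * mult, inverse = TRUE)) / n
}

#' Fourth-order spectral derivative of a periodic beat
#'
#' Differentiates one beat of a periodic signal four times in the frequency
#' domain: harmonic `k` is multiplied by `(i 2 pi k / T)^4 = (2 pi k / T)^4`.
#' Spectral differentiation on the periodic beat is used (rather than finite
#' differences on the raw trace) for consistency with the harmonic filtering
#' applied to the result.
#'
#' @param x numeric vector, one full period of samples (>= 8).
#' @param T period in seconds.
#' @return Numeric vector, the fourth derivative on the same grid.
#' @export
derivative4 <- function(x, T) {
  spectral_derivative(x, T, order = 4L)
}
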