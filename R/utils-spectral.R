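# Low-level circular and spectral primitives shared by the generators and
# the feature extractors. None of the installed signal-processing packages
# provide a Hilbert analytic signal or a Welch-averaged periodogram, so both
# are implemented here directly on top of stats::fft.

#' Wrap angles to (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @export
wrap_phase <- function(x) {
  w <- ((x + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler. `kappa = 0` returns uniform angles, the
#' zero-concentration limit.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration parameter, >= 0.
#' @return numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0, is.finite(mu))
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(wrap_phase(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nacc <- sum(ok)
    if (nacc > 0) {
      theta <- sign(u3[ok] - 0.5) * acos(pmax(-1, pmin(1, f[ok])))
      out[(got + 1L):(got + nacc)] <- theta
      got <- got + nacc
    }
  }
  wrap_phase(out + mu)
}

#' Mean resultant length of a von Mises distribution
#'
#' The population vector length `R(kappa) = I1(kappa)/I0(kappa)` (ratio of
#' modified Bessel functions); the oracle against which empirical coupling
#' vector lengths are checked.
#'
#' @param kappa concentration, >= 0.
#' @return expected vector length in `[0, 1)`.
#' @export
von_mises_R <- function(kappa) {
  stopifnot(all(kappa >= 0))
  # scaled Bessel ratio is stable for large kappa
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' Invert the mean resultant length to a concentration
#'
#' Numeric inverse of [von_mises_R()] by root finding; used when a target
#' coupling vector length must be realized as a von Mises concentration.
#'
#' @param R target vector length in `[0, 1)`.
#' @return concentration kappa >= 0.
#' @export
von_mises_kappa <- function(R) {
  stopifnot(R >= 0, R < 1)
  if (R < 1e-8) return(0)
  stats::uniroot(function(k) von_mises_R(k) - R, c(1e-8, 1e4), tol = 1e-10)$root
}

# Analytic signal via one-sided FFT (Hilbert construction).
analytic_signal <- function(x) {
  n <- length(x)
  stopifnot(n >= 2)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Zero-phase band-pass by zeroing FFT bins outside [lo, hi] Hz.
fft_bandpass <- function(x, fs, lo, hi) {
  stopifnot(lo < hi, lo >= 0, hi <= fs / 2)
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  f[f > fs / 2] <- f[f > fs / 2] - fs   # two-sided frequency axis
  keep <- abs(f) >= lo & abs(f) <= hi
  X <- stats::fft(x)
  X[!keep] <- 0 + 0i
  Re(stats::fft(X, inverse = TRUE) / n)
}

#' Welch-averaged power spectral density
#'
#' Hann-windowed segments with 50% overlap, one-sided density normalisation.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param nperseg segment length in samples; default `4 * fs` (0.25 Hz bins).
#' @return data.frame with columns `freq` (Hz) and `power`.
#' @export
welch_psd <- function(x, fs, nperseg = round(4 * fs)) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  stopifnot(nperseg >= 8)
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1))  # Hann
  scale <- fs * sum(w^2)
  nfreq <- floor(nperseg / 2) + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg))^2 / scale
    acc <- acc + P[seq_len(nfreq)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when even)
  if (nperseg %% 2 == 0) {
    psd[2:(nfreq - 1L)] <- 2 * psd[2:(nfreq - 1L)]
  } else {
    psd[2:nfreq] <- 2 * psd[2:nfreq]
  }
  data.frame(freq = (seq_len(nfreq) - 1) * fs / nperseg, power = psd)
}

# 1/f^chi background: spectrally shaped white noise (FFT amplitudes scaled
# by f^(-chi/2)), unit-variance output. chi = 0 returns white noise.
colored_noise <- function(n, fs, chi) {
  stopifnot(n >= 2, chi >= 0)
  z <- stats::rnorm(n)
  if (chi == 0) return(z)
  f <- (seq_len(n) - 1) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]
  g <- c(0, f[-1]^(-chi / 2))            # kill DC
  x <- Re(stats::fft(stats::fft(z) * g, inverse = TRUE) / n)
  x / stats::sd(x)
}
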