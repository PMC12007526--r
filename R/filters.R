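#' Zero-phase FIR filtering via the frequency domain
#'
#' Applies the magnitude response of a linear-phase FIR filter with exactly
#' zero phase. The signal is zero-padded by the filter length on both ends,
#' transformed, multiplied by the (real, symmetric) magnitude response of the
#' filter taps evaluated on the FFT grid, and transformed back.
#'
#' @param x numeric signal.
#' @param taps FIR filter coefficients.
#' @return filtered signal, same length as `x`.
#' @keywords internal
zero_phase_apply <- function(x, taps) {
  n <- length(x)
  npad <- length(taps)
  nfft <- stats::nextn(n + 2L * npad, 2)
  xp <- c(rep(0, npad), x, rep(0, nfft - n - npad))
  H <- stats::fft(c(taps, rep(0, nfft - length(taps))))
  y <- Re(stats::fft(stats::fft(xp) * Mod(H), inverse = TRUE)) / nfft
  y[(npad + 1L):(npad + n)]
}

#' Measure the magnitude response of FIR taps at given frequencies
#' @keywords internal
fir_gain <- function(taps, freqs_hz, fs) {
  k <- seq_along(taps) - 1
  vapply(freqs_hz, function(f) {
    Mod(sum(taps * exp(-2i * pi * f * k / fs)))
  }, numeric(1))
}

#' Design the ASSR band-pass filter
#'
#' A 512-tap FIR band-pass whose single-pass -3 dB edges sit at the requested
#' frequencies (defaults 28 and 56 Hz, one octave around 40 Hz). A windowed
#' design puts its -6 dB point at the nominal cutoff, so the design cutoffs
#' are calibrated by fixed-point iteration until the measured -3 dB edges
#' match the request to within 0.05 Hz.
#'
#' @param fs sampling rate in Hz.
#' @param lo,hi target -3 dB edges in Hz.
#' @param n_taps filter length (default 512).
#' @return numeric vector of taps with attributes `lo`, `hi`, `fs`.
#' @export
design_assr_bandpass <- function(fs = 1250, lo = 28, hi = 56, n_taps = 512) {
  edge_at <- function(taps, target, from, to) {
    f <- seq(from, to, by = 0.01)
    g <- fir_gain(taps, f, fs)
    i <- which(g >= 10^(-3 / 20))
    if (!length(i)) return(NA_real_)
    if (target < (from + to) / 2) f[min(i)] else f[max(i)]
  }
  a <- lo; b <- hi
  taps <- NULL
  for (iter in 1:12) {
    taps <- signal::fir1(n_taps - 1, c(a, b) / (fs / 2), type = "pass")
    e1 <- edge_at(taps, lo, lo - 10, 40)
    e2 <- edge_at(taps, hi, 40, hi + 12)
    if (is.na(e1) || is.na(e2)) stop("band-pass design failed")
    if (abs(e1 - lo) < 0.05 && abs(e2 - hi) < 0.05) break
    a <- a + (lo - e1)
    b <- b + (hi - e2)
  }
  structure(as.numeric(taps), lo = lo, hi = hi, fs = fs)
}

#' Design a low-pass FIR (used for artifact regressors)
#' @keywords internal
design_lowpass <- function(fs, cutoff_hz, n_taps = 1024) {
  as.numeric(signal::fir1(n_taps - 1, cutoff_hz / (fs / 2), type = "low"))
}

#' Analytic signal via the Hilbert transform
#'
#' Standard frequency-domain construction: double the positive frequencies,
#' zero the negative ones.
#'
#' @param x real signal.
#' @return complex vector, `Re` equal to `x`.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Power-law (1/f^slope) noise
#'
#' @param n samples.
#' @param fs sampling rate (Hz).
#' @param slope spectral exponent of the power spectrum (1 = pink).
#' @param sd target standard deviation of the output.
#' @param white_frac fraction of variance contributed by a white floor.
#' @return numeric vector with sd approximately `sd`.
#' @export
powerlaw_noise <- function(n, fs, slope = 1, sd = 1, white_frac = 0.2) {
  nfft <- stats::nextn(n, 2)
  f <- seq(0, fs / 2, length.out = nfft / 2 + 1)
  shape <- c(0, f[-1]^(-slope / 2))
  half <- (stats::rnorm(nfft / 2 + 1) + 1i * stats::rnorm(nfft / 2 + 1)) * shape
  half[1] <- 0
  half[nfft / 2 + 1] <- Re(half[nfft / 2 + 1])
  spec <- c(half, Conj(rev(half[2:(nfft / 2)])))
  x <- Re(stats::fft(spec, inverse = TRUE))[1:n]
  x <- x / stats::sd(x)
  w <- stats::rnorm(n)
  y <- sqrt(1 - white_frac) * x + sqrt(white_frac) * w
  sd * y / stats::sd(y)
}

#' Real cepstrum
#'
#' Inverse FFT of the log magnitude spectrum; peaks mark the quefrency of
#' periodic structure (here: heartbeat intervals).
#'
#' @param x real signal.
#' @return numeric vector of cepstral coefficients (same length as `x`).
#' @export
real_cepstrum <- function(x) {
  X <- Mod(stats::fft(x - mean(x)))
  Re(stats::fft(log(X + 1e-12), inverse = TRUE)) / length(x)
}

#' Wrap an angle into (-pi, pi]
#' @keywords internal
wrap_angle <- function(phi) {
  w <- (phi + pi) %% (2 * pi) - pi
  ifelse(w == -pi, pi, w)
}
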