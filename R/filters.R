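#' Windowed-sinc FIR lowpass design (Hamming window)
#'
#' Linear-phase type-I FIR: `order + 1` taps, symmetric about the centre tap,
#' normalized to unit DC gain. The preprocessing convention is order = 2 * fs
#' taps at the record's native sampling rate.
#'
#' @param order filter order (even); the kernel has `order + 1` taps.
#' @param fc cutoff frequency, Hz.
#' @param fs sampling rate, Hz.
#' @return numeric vector of taps.
#' @export
fir_lowpass <- function(order, fc, fs) {
  if (order %% 2 != 0) order <- order + 1
  m <- order / 2
  k <- seq(-m, m)
  h <- 2 * fc / fs * sinc(2 * fc / fs * k)
  w <- 0.54 + 0.46 * cos(pi * k / m)  # Hamming
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Butterworth highpass design (bilinear transform)
#'
#' Designs a digital Butterworth highpass from the analog prototype
#' (poles on the unit circle in the left half-plane), with frequency
#' prewarping. Gain is normalized to unity at the Nyquist frequency.
#'
#' @param order filter order.
#' @param fc cutoff (-3 dB) frequency, Hz.
#' @param fs sampling rate, Hz.
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
butter_highpass <- function(order, fc, fs) {
  stopifnot(fc > 0, fc < fs / 2)
  # analog lowpass prototype poles (wc = 1)
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  wc <- 2 * fs * tan(pi * fc / fs)  # prewarped cutoff, rad/s
  # lowpass -> highpass: s -> wc/s; poles wc/p, n zeros at s = 0
  p_hp <- wc / p_lp
  z_hp <- rep(0 + 0i, order)
  # bilinear: s = 2*fs*(z-1)/(z+1)  =>  z = (2fs + s)/(2fs - s)
  fs2 <- 2 * fs
  pz <- (fs2 + p_hp) / (fs2 - p_hp)
  zz <- (fs2 + z_hp) / (fs2 - z_hp)
  b <- Re(poly_from_roots(zz))
  a <- Re(poly_from_roots(pz))
  # unity gain at Nyquist (z = -1)
  zm1 <- (-1) ^ (seq_along(b) - 1)
  g <- sum(b * zm1) / sum(a * zm1)
  list(b = b / g / a[1], a = a / a[1])
}

poly_from_roots <- function(r) {
  p <- c(1 + 0i)
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Frequency response of a rational (IIR) digital filter
#' @param b,a coefficient vectors.
#' @param f frequencies (Hz) at which to evaluate.
#' @param fs sampling rate, Hz.
#' @return complex response at each frequency.
#' @export
freqz_response <- function(b, a, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  num <- vapply(z, function(zi) sum(b * zi ^ (seq_along(b) - 1)), complex(1))
  den <- vapply(z, function(zi) sum(a * zi ^ (seq_along(a) - 1)), complex(1))
  num / den
}

#' Analog Butterworth highpass magnitude response
#'
#' The design (analog prototype) magnitude \eqn{|H(f)|^2 = 1 / (1 + (fc/f)^{2n})}
#' that the printed attenuation figures describe.
#'
#' @param f frequency, Hz.
#' @param fc cutoff frequency, Hz.
#' @param order filter order.
#' @return magnitude (linear units).
#' @export
butter_highpass_analog_mag <- function(f, fc, order) {
  1 / sqrt(1 + (fc / f) ^ (2 * order))
}

# Single-pass IIR filtering (direct form II transposed, C++ kernel)
iir_filter <- function(b, a, x) iir_filter_cpp(b, a, x)

#' Zero-phase forward-backward IIR filtering
#'
#' Filters forward and backward with odd-reflection padding at both ends to
#' suppress edge transients. The pipeline passes a padding of about three
#' seconds of samples; the default is a multiple of the filter length,
#' capped by the signal length.
#'
#' @param b,a filter coefficients.
#' @param x signal.
#' @param padlen reflection pad length in samples.
#' @return filtered signal, same length as `x`.
#' @export
filtfilt_iir <- function(b, a, x, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- min(n - 1L, 3L * 10L * max(length(a), length(b)))
  if (padlen > 0) {
    pre <- 2 * x[1] - x[seq(padlen + 1, 2)]
    post <- 2 * x[n] - x[seq(n - 1, n - padlen)]
    xp <- c(pre, x, post)
  } else xp <- x
  y <- iir_filter(b, a, xp)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

# Centered (zero-phase) FIR filtering via FFT convolution; kernel must be
# symmetric with odd length.
fir_filter_centered <- function(h, x) {
  n <- length(x); L <- length(h); m <- (L - 1) / 2
  nfft <- 2 ^ ceiling(log2(n + L))
  X <- stats::fft(c(x, rep(0, nfft - n)))
  H <- stats::fft(c(h, rep(0, nfft - L)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
  y[(m + 1):(m + n)]
}

#' Fourier-domain resampling
#'
#' Anti-aliased resampling of a signal to `n_new` samples by spectral
#' truncation/zero-padding (the classical FFT resample).
#'
#' @param x signal.
#' @param n_new output length.
#' @return resampled signal of length `n_new`.
#' @export
resample_fft <- function(x, n_new) {
  n <- length(x)
  if (n_new == n) return(x)
  X <- stats::fft(x)
  Y <- complex(n_new)
  keep <- min(n, n_new)
  half <- floor((keep - 1) / 2)
  Y[1] <- X[1]
  if (half > 0) {
    Y[2:(half + 1)] <- X[2:(half + 1)]
    Y[(n_new - half + 1):n_new] <- X[(n - half + 1):n]
  }
  if (keep %% 2 == 0) {
    # split the shared Nyquist bin symmetrically
    ny <- keep / 2 + 1
    if (n_new < n) {
      Y[ny] <- Re(X[ny]) # real projection keeps the output real
    } else {
      Y[ny] <- X[ny] / 2
      Y[n_new - keep / 2 + 1] <- Conj(X[ny]) / 2
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}
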