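#' Morlet wavelet analysis grid
#'
#' 49 logarithmically spaced frequencies (8 per octave, endpoints inclusive)
#' over 0.5-32 Hz. Each frequency is analysed with a 7-cycle complex Morlet
#' kernel truncated at +/- 3 temporal SDs; the analysis window length equals
#' the kernel support and windows overlap by 75%.
#'
#' @param f_lo,f_hi frequency range, Hz.
#' @param per_octave frequencies per octave.
#' @param n_cycles Morlet cycles (sets sigma_t = n_cycles / (2 pi f)).
#' @param support_sd kernel truncation in temporal SDs (each side).
#' @param overlap window overlap fraction.
#' @return list of class \code{wavelet_grid} with \code{frequencies} and
#'   parameters.
#' @export
wavelet_grid <- function(f_lo = 0.5, f_hi = 32, per_octave = 8, n_cycles = 7,
                         support_sd = 3, overlap = 0.75) {
  freqs <- 2 ^ seq(log2(f_lo), log2(f_hi), by = 1 / per_octave)
  structure(list(frequencies = freqs, per_octave = per_octave,
                 n_cycles = n_cycles, support_sd = support_sd,
                 overlap = overlap),
            class = "wavelet_grid")
}

#' Canonical six-octave band set
#'
#' s [0.5,1), delta1 [1,2), delta2 [2,4), theta [4,8), alpha-sigma [8,16),
#' beta [16,32) Hz; lower bounds inclusive, upper bounds exclusive.
#'
#' @return named list of c(lo, hi) band edges.
#' @export
band_set <- function() {
  list(s = c(0.5, 1), delta1 = c(1, 2), delta2 = c(2, 4), theta = c(4, 8),
       alphasigma = c(8, 16), beta = c(16, 32))
}

# complex Morlet kernel at frequency f (unit-energy not enforced; the PSD
# normalization uses the kernel's own energy)
morlet_kernel <- function(f, fs, n_cycles = 7, support_sd = 3) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(support_sd * sigma_t * fs)
  t <- (-half:half) / fs
  exp(2i * pi * f * t) * exp(-t ^ 2 / (2 * sigma_t ^ 2))
}

#' Morlet-wavelet power spectral density of a record
#'
#' Per channel and frequency: the signal is convolved with the Morlet kernel,
#' power is averaged over analysis windows (window length = kernel support,
#' 75% overlap) that are at least 80% artifact-free and fully covered by the
#' convolution's valid region, and calibrated to microvolt^2/Hz using the
#' kernel's one-sided equivalent noise bandwidth (a flat unit-variance white
#' input integrates back to its variance).
#'
#' @param record an \code{eeg_record}.
#' @param grid a \code{wavelet_grid}.
#' @param min_usable_fraction validity threshold per window.
#' @return matrix channels x frequencies of PSD values (\code{NA} where a
#'   frequency has no valid window), with the frequency vector as
#'   \code{attr(,"frequencies")}.
#' @export
morlet_psd <- function(record, grid = wavelet_grid(),
                       min_usable_fraction = 0.8) {
  fs <- record$fs
  X <- record$data
  nch <- nrow(X); n <- ncol(X)
  freqs <- grid$frequencies
  if (max(freqs) > fs / 2) stop("morlet_psd: grid exceeds the Nyquist frequency")
  nfreq <- length(freqs)
  out <- matrix(NA_real_, nch, nfreq)
  nfft <- 2 ^ ceiling(log2(2 * n))
  Xf <- matrix(0i, nfft, nch)
  for (ch in seq_len(nch)) Xf[, ch] <- stats::fft(c(X[ch, ], rep(0, nfft - n)))
  cmask <- c(0, cumsum(record$artifact_mask))
  for (k in seq_len(nfreq)) {
    psi <- morlet_kernel(freqs[k], fs, grid$n_cycles, grid$support_sd)
    L <- length(psi)
    if (L > n) next # kernel longer than the record: no valid window
    energy <- sum(Mod(psi) ^ 2)
    Hf <- stats::fft(c(Conj(rev(psi)), rep(0, nfft - L)))
    hop <- max(1L, round(L * (1 - grid$overlap)))
    starts <- seq(1L, n - L + 1L, by = hop)
    frac <- (cmask[starts + L] - cmask[starts]) / L
    starts <- starts[frac >= min_usable_fraction]
    if (!length(starts)) next
    for (ch in seq_len(nch)) {
      conv <- stats::fft(Xf[, ch] * Hf, inverse = TRUE) / nfft
      pw <- Mod(conv[L:n]) ^ 2  # index s <-> kernel aligned with [s, s+L-1]
      out[ch, k] <- mean(pw[starts]) * 2 / (fs * energy)
    }
  }
  dimnames(out) <- list(record$channel_labels, NULL)
  attr(out, "frequencies") <- freqs
  out
}

#' Band power from a PSD on the canonical grid
#'
#' Absolute power integrates the PSD across each band with the trapezoid rule
#' on the log-spaced bins; relative power divides by the total integrated
#' broadband power (relative values sum to 1).
#'
#' @param psd matrix channels x frequencies with a \code{frequencies}
#'   attribute (or a bare vector for one channel).
#' @param bands band list as from \code{\link{band_set}}.
#' @param relative logical; return band power relative to broadband power.
#' @return matrix channels x bands.
#' @export
band_power <- function(psd, bands = band_set(), relative = FALSE) {
  if (is.null(dim(psd))) psd <- matrix(psd, 1, dimnames = NULL)
  freqs <- attr(psd, "frequencies")
  if (is.null(freqs)) stop("band_power: psd needs a 'frequencies' attribute")
  trap <- function(v, f) {
    if (length(f) < 2) return(0)
    sum(diff(f) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
  }
  nch <- nrow(psd)
  out <- matrix(NA_real_, nch, length(bands),
                dimnames = list(rownames(psd), names(bands)))
  for (ch in seq_len(nch)) {
    v <- psd[ch, ]
    if (anyNA(v)) next
    for (b in seq_along(bands)) {
      sel <- freqs >= bands[[b]][1] & freqs <= bands[[b]][2]
      out[ch, b] <- trap(v[sel], freqs[sel])
    }
    if (relative) {
      tot <- trap(v, freqs)
      if (tot <= 0) stop("band_power: zero total power; relative power undefined")
      out[ch, ] <- out[ch, ] / tot
    }
  }
  out
}

#' Debiased weighted phase lag index
#'
#' Cross-spectral densities are estimated in 5 s windows (50% overlap) from
#' 2 s Hamming segments with 50% overlap, evaluated by direct DFT at the
#' wavelet grid frequencies. Across windows-as-observations the debiased
#' WPLI-square estimator
#' \deqn{\sum_{j \ne k} Im(X_j) Im(X_k) / \sum_{j \ne k} |Im(X_j) Im(X_k)|}
#' is formed per frequency bin, then averaged within bands (bins assigned
#' lower-inclusive / upper-exclusive).
#'
#' @param record an \code{eeg_record}.
#' @param grid a \code{wavelet_grid} (frequency bins).
#' @param pairs data.frame from \code{\link{pair_classification}}; pairs of
#'   every class are computed (class averaging happens downstream).
#' @param window_s,seg_s outer window and inner segment lengths, seconds.
#' @param bands band list for the band averages.
#' @return list with \code{pair_band} (matrix pairs x bands), \code{pairs}
#'   (the input pair table), and \code{n_windows}. Values are \code{NA} with
#'   fewer than 2 valid windows.
#' @export
dwpli <- function(record, grid = wavelet_grid(), pairs = NULL,
                  window_s = 5, seg_s = 2, bands = band_set()) {
  fs <- record$fs
  X <- record$data
  nch <- nrow(X); n <- ncol(X)
  if (is.null(pairs)) pairs <- pair_classification()
  freqs <- grid$frequencies
  wl <- round(window_s * fs); sl <- round(seg_s * fs)
  seg_hop <- sl %/% 2L
  # unique 2 s segments on the record timeline
  seg_starts <- seq(1L, n - sl + 1L, by = seg_hop)
  # valid outer windows: fully usable
  win_starts <- clean_window_starts(record$artifact_mask, wl, wl %/% 2L)
  # map segments into windows (segment fully inside the window)
  win_of_seg <- lapply(win_starts, function(ws)
    which(seg_starts >= ws & (seg_starts + sl - 1L) <= ws + wl - 1L))
  keep_w <- lengths(win_of_seg) > 0
  win_starts <- win_starts[keep_w]; win_of_seg <- win_of_seg[keep_w]
  nwin <- length(win_starts)
  npair <- nrow(pairs)
  out <- matrix(NA_real_, npair, length(bands),
                dimnames = list(NULL, names(bands)))
  if (nwin < 2)
    return(list(pair_band = out, pairs = pairs, n_windows = nwin))
  used_segs <- sort(unique(unlist(win_of_seg)))
  seg_map <- lapply(win_of_seg, match, used_segs)
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:(sl - 1)) / (sl - 1))
  E <- exp(-2i * pi * outer((0:(sl - 1)) / fs, freqs)) * ham  # sl x nfreq
  nseg <- length(used_segs)
  D <- array(0i, c(nch, length(freqs), nseg))
  for (g in seq_len(nseg)) {
    s0 <- seg_starts[used_segs[g]]
    seg <- X[, s0:(s0 + sl - 1L), drop = FALSE]
    D[, , g] <- seg %*% E
  }
  i1 <- pairs$i; i2 <- pairs$j
  imcs <- matrix(0, npair, nwin)  # workspace per frequency
  band_of_bin <- rep(NA_integer_, length(freqs))
  for (b in seq_along(bands))
    band_of_bin[freqs >= bands[[b]][1] & freqs < bands[[b]][2]] <- b
  acc <- array(0, c(npair, length(bands), 2))  # sums and counts per band
  for (k in seq_along(freqs)) {
    dk <- D[, k, ]                     # nch x nseg
    if (is.null(dim(dk))) dk <- matrix(dk, nch, nseg)
    cross <- Im(dk[i1, , drop = FALSE] * Conj(dk[i2, , drop = FALSE]))
    for (w in seq_len(nwin))
      imcs[, w] <- rowMeans(cross[, seg_map[[w]], drop = FALSE])
    sI <- rowSums(imcs); sI2 <- rowSums(imcs ^ 2); sA <- rowSums(abs(imcs))
    den <- sA ^ 2 - sI2
    v <- ifelse(den > 0, (sI ^ 2 - sI2) / den, 0)
    b <- band_of_bin[k]
    if (!is.na(b)) {
      acc[, b, 1] <- acc[, b, 1] + v
      acc[, b, 2] <- acc[, b, 2] + 1
    }
  }
  for (b in seq_along(bands))
    if (acc[1, b, 2] > 0) out[, b] <- acc[, b, 1] / acc[, b, 2]
  list(pair_band = out, pairs = pairs, n_windows = nwin)
}

#' Spectral peak above the aperiodic background
#'
#' Channel-averaged, log-scaled PSD: a log-log linear background is fitted by
#' least squares and the most prominent local maximum of the residual is
#' returned, or \code{NA} when no local maximum exceeds the prominence
#' threshold. A simplified stand-in for full peak-model fitting.
#'
#' @param psd vector (or channels x frequencies matrix, averaged) with a
#'   \code{frequencies} attribute.
#' @param prominence minimum residual height in log10 power units.
#' @return peak frequency in Hz, or \code{NA}.
#' @export
spectral_peak <- function(psd, prominence = 0.1) {
  freqs <- attr(psd, "frequencies")
  v <- if (is.null(dim(psd))) psd else colMeans(psd, na.rm = TRUE)
  if (is.null(freqs)) stop("spectral_peak: psd needs a 'frequencies' attribute")
  ok <- is.finite(v) & v > 0
  lf <- log10(freqs[ok]); lp <- log10(v[ok])
  if (length(lf) < 5) return(NA_real_)
  fit <- stats::lm.fit(cbind(1, lf), lp)
  resid <- lp - cbind(1, lf) %*% fit$coefficients
  r <- as.numeric(resid)
  locmax <- which(r > c(-Inf, r[-length(r)]) & r >= c(r[-1], -Inf))
  locmax <- locmax[r[locmax] > prominence]
  locmax <- locmax[locmax > 1 & locmax < length(r)]
  if (!length(locmax)) return(NA_real_)
  10 ^ lf[locmax[which.max(r[locmax])]]
}
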