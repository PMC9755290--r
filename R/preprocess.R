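#' Preprocessing filter specification
#'
#' The pipeline's filtering convention: a 45 Hz linear-phase FIR lowpass whose
#' order is twice the sampling rate (Hamming-windowed sinc, applied centred so
#' the net result is zero phase), and a 0.4 Hz 5th-order Butterworth highpass.
#' The Butterworth's design response attenuates 0.5 Hz slow oscillations by
#' about 0.44 dB while strongly suppressing sub-0.1 Hz drift.
#'
#' @param lowpass_hz FIR lowpass cutoff, Hz.
#' @param highpass_hz Butterworth highpass cutoff, Hz.
#' @param butter_order Butterworth order.
#' @param fir_order_factor FIR order as a multiple of the sampling rate.
#' @return list of class \code{filter_spec}.
#' @export
filter_spec <- function(lowpass_hz = 45, highpass_hz = 0.4,
                        butter_order = 5, fir_order_factor = 2) {
  structure(list(lowpass_hz = lowpass_hz, highpass_hz = highpass_hz,
                 butter_order = butter_order,
                 fir_order_factor = fir_order_factor),
            class = "filter_spec")
}

#' Bandpass-filter a record (lowpass FIR + highpass Butterworth)
#'
#' The FIR lowpass is symmetric and applied centred (zero phase). The
#' Butterworth highpass is applied forward-backward by default (zero phase);
#' \code{zero_phase = FALSE} applies it single-pass, matching the design
#' response the attenuation figure describes. The artifact mask is unchanged:
#' masks are annotations, filtering runs across the whole signal.
#'
#' @param record an \code{eeg_record}.
#' @param spec a \code{filter_spec}.
#' @param zero_phase logical; forward-backward Butterworth if \code{TRUE}.
#' @param highpass logical; set \code{FALSE} to skip the highpass.
#' @return the filtered \code{eeg_record}.
#' @export
bandpass <- function(record, spec = filter_spec(), zero_phase = TRUE,
                     highpass = TRUE) {
  fs <- record$fs
  if (fs <= 2 * spec$lowpass_hz)
    stop(sprintf("bandpass: fs = %g Hz too low for a %g Hz lowpass (need fs > %g)",
                 fs, spec$lowpass_hz, 2 * spec$lowpass_hz))
  h <- fir_lowpass(round(spec$fir_order_factor * fs), spec$lowpass_hz, fs)
  bw <- butter_highpass(spec$butter_order, spec$highpass_hz, fs)
  out <- record
  padlen <- min(ncol(record$data) - 1L, as.integer(3 * fs))
  for (ch in seq_len(nrow(record$data))) {
    x <- fir_filter_centered(h, record$data[ch, ])
    if (highpass) {
      x <- if (zero_phase) filtfilt_iir(bw$b, bw$a, x, padlen = padlen)
           else iir_filter(bw$b, bw$a, x)
    }
    out$data[ch, ] <- x
  }
  out
}

#' Re-reference a record to the common average
#'
#' Subtracts the instantaneous mean across channels, so each sample's channel
#' mean is zero afterwards. Idempotent.
#'
#' @param record an \code{eeg_record} with at least 2 channels.
#' @return the re-referenced record.
#' @export
average_reference <- function(record) {
  if (nrow(record$data) < 2)
    stop("average_reference: need at least 2 channels")
  record$data <- sweep(record$data, 2, colMeans(record$data))
  record
}

#' Data-sufficiency policy for the lowest analysis frequency
#'
#' A recording-state is usable when it yields at least
#' \code{min_valid_windows} windows of the lowest-frequency wavelet window
#' length (default 10.9 s, 75% overlap), each at least 80% artifact-free.
#'
#' @param min_valid_windows minimum number of valid windows.
#' @param window_usable_fraction minimum usable fraction within a window.
#' @param lowest_frequency_window_s window length at the lowest frequency, s.
#' @param overlap_fraction window overlap fraction.
#' @return list of class \code{validity_policy}.
#' @export
validity_policy <- function(min_valid_windows = 15L,
                            window_usable_fraction = 0.80,
                            lowest_frequency_window_s = 10.9,
                            overlap_fraction = 0.75) {
  structure(list(min_valid_windows = as.integer(min_valid_windows),
                 window_usable_fraction = window_usable_fraction,
                 lowest_frequency_window_s = lowest_frequency_window_s,
                 overlap_fraction = overlap_fraction),
            class = "validity_policy")
}

#' Check whether a record has enough usable data
#'
#' Counts sliding windows of the lowest-frequency length (hop =
#' (1 - overlap) * length) whose usable fraction meets the policy, and reports
#' the analytic minimum usable duration
#' \code{usable_fraction * (L + (k - 1) * hop)} implied by requiring `k` valid
#' windows.
#'
#' @param record an \code{eeg_record}.
#' @param policy a \code{validity_policy}.
#' @return list with \code{usable}, \code{n_valid_windows},
#'   \code{min_required_s}.
#' @export
check_sufficiency <- function(record, policy = validity_policy()) {
  fs <- record$fs
  L <- round(policy$lowest_frequency_window_s * fs)
  hop <- max(1L, round((1 - policy$overlap_fraction) * L))
  n <- n_samples(record)
  mask <- record$artifact_mask
  nwin <- 0L
  if (n >= L) {
    cm <- c(0, cumsum(mask))
    starts <- seq(1L, n - L + 1L, by = hop)
    frac <- (cm[starts + L] - cm[starts]) / L
    nwin <- sum(frac >= policy$window_usable_fraction)
  }
  Ls <- policy$lowest_frequency_window_s
  hop_s <- (1 - policy$overlap_fraction) * Ls
  min_required <- policy$window_usable_fraction *
    (Ls + (policy$min_valid_windows - 1L) * hop_s)
  list(usable = nwin >= policy$min_valid_windows,
       n_valid_windows = as.integer(nwin),
       min_required_s = min_required)
}

#' Downsample a record with Fourier-domain anti-aliasing
#'
#' The artifact mask is resampled conservatively: an output sample is usable
#' only if every input sample in its footprint is usable (logical AND).
#'
#' @param record an \code{eeg_record}.
#' @param target_fs target sampling rate, Hz (must not exceed the current one).
#' @return the downsampled record.
#' @export
downsample <- function(record, target_fs) {
  fs <- record$fs
  if (target_fs > fs) stop("downsample: target_fs exceeds current fs")
  if (target_fs == fs) return(record)
  n <- n_samples(record)
  n_new <- round(n * target_fs / fs)
  out <- record
  out$data <- t(apply(record$data, 1, resample_fft, n_new = n_new))
  out$fs <- target_fs
  # block-AND the mask: output sample i covers input [i*n/n_new, (i+1)*n/n_new)
  edges <- floor(seq(0, n, length.out = n_new + 1))
  cm <- c(0, cumsum(!record$artifact_mask))
  bad <- (cm[pmin(edges[-1], n) + 1] - cm[edges[-length(edges)] + 1]) > 0
  out$artifact_mask <- !bad
  out
}
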