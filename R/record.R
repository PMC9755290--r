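#' Construct a multichannel EEG record
#'
#' The package's canonical container: a channels-by-samples matrix in microvolts
#' plus sampling rate, 10-20 channel labels, a per-sample artifact mask
#' (\code{TRUE} = usable) and participant/cohort/state metadata.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz. Rates outside the common set
#'   (125, 200, 250, 256, 500, 512) are accepted with a warning.
#' @param channel_labels character vector of 10-20 labels, one per row.
#' @param artifact_mask logical vector, one element per sample; \code{TRUE}
#'   marks usable data. Defaults to all usable.
#' @param participant_id,cohort,state metadata strings; \code{state} must be
#'   \code{"wake"} or \code{"nrem"}.
#' @return An object of class \code{eeg_record}.
#' @export
eeg_record <- function(data, fs, channel_labels = NULL, artifact_mask = NULL,
                       participant_id = NA_character_, cohort = NA_character_,
                       state = NA_character_) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("eeg_record: data must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("eeg_record: fs must be a positive scalar")
  common_fs <- c(125, 200, 250, 256, 500, 512)
  if (!fs %in% common_fs)
    warning(sprintf("unusual sampling rate %g Hz accepted", fs))
  n <- ncol(data)
  if (is.null(artifact_mask)) artifact_mask <- rep(TRUE, n)
  if (length(artifact_mask) != n)
    stop("eeg_record: artifact mask length must equal the sample count")
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data))
    stop("eeg_record: one channel label per data row required")
  if (!is.na(state) && !state %in% c("wake", "nrem"))
    stop("eeg_record: state must be 'wake' or 'nrem'")
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 artifact_mask = as.logical(artifact_mask),
                 participant_id = participant_id, cohort = cohort,
                 state = state),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d ch x %d samples @ %g Hz (%.1f s), %.1f%% usable\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              100 * mean(x$artifact_mask)))
  cat(sprintf("  participant=%s cohort=%s state=%s\n",
              x$participant_id, x$cohort, x$state))
  invisible(x)
}

#' Number of samples in a record
#' @param record an \code{eeg_record}.
#' @export
n_samples <- function(record) ncol(record$data)

#' Usable (artifact-free) duration of a record in seconds
#' @param record an \code{eeg_record}.
#' @export
usable_length_s <- function(record) sum(record$artifact_mask) / record$fs

# Half-open [start, end) 0-based sample intervals -> logical mask (TRUE usable)
mask_from_intervals <- function(n, intervals) {
  mask <- rep(TRUE, n)
  if (length(intervals)) {
    for (iv in intervals) {
      s <- max(0L, iv[1]); e <- min(n, iv[2])
      if (e > s) mask[(s + 1L):e] <- FALSE
    }
  }
  mask
}
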