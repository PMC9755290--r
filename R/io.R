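#' Write a record in the internal fixture format
#'
#' One little-endian float64 binary array (channel-major) plus a JSON sidecar
#' carrying sampling rate, labels, metadata and the artifact mask as
#' half-open 0-based [start, end) sample intervals.
#'
#' @param record an \code{eeg_record}.
#' @param dir output directory.
#' @param stem file stem; defaults to participant_state.
#' @return invisibly, the path of the binary file.
#' @export
write_fixture <- function(record, dir, stem = NULL) {
  if (is.null(stem))
    stem <- paste(record$participant_id, record$state, sep = "_")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bin <- file.path(dir, paste0(stem, ".bin"))
  con <- file(bin, "wb")
  writeBin(as.numeric(t(record$data)), con, size = 8, endian = "little")
  close(con)
  bad <- !record$artifact_mask
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  iv <- cbind(starts, ends)[r$values, , drop = FALSE]
  meta <- list(n_channels = nrow(record$data), n_samples = ncol(record$data),
               fs = record$fs, channel_labels = record$channel_labels,
               participant_id = record$participant_id, cohort = record$cohort,
               state = record$state,
               masked_intervals = if (nrow(iv)) unname(apply(iv, 1, as.list))
                                  else list())
  jsonlite::write_json(meta, file.path(dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(bin)
}

#' Read a record from the internal fixture format
#'
#' @param path path to the \code{.bin} file (the \code{.json} sidecar must sit
#'   beside it).
#' @return an \code{eeg_record}.
#' @export
read_fixture <- function(path) {
  if (!grepl("\\.bin$", path))
    stop("read_fixture: expected a .bin fixture file")
  side <- sub("\\.bin$", ".json", path)
  if (!file.exists(path) || !file.exists(side))
    stop("read_fixture: missing fixture file or sidecar for ", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  con <- file(path, "rb")
  v <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  close(con)
  if (length(v) != n)
    stop(sprintf("read_fixture: malformed file (expected %d doubles, got %d at offset %d)",
                 n, length(v), length(v) * 8))
  data <- matrix(v, nrow = meta$n_channels, byrow = TRUE)
  iv <- meta$masked_intervals
  ivl <- if (length(iv)) {
    if (is.data.frame(iv)) lapply(seq_len(nrow(iv)), function(i) unlist(iv[i, ]))
    else lapply(iv, unlist)
  } else list()
  mask <- mask_from_intervals(meta$n_samples, ivl)
  suppressWarnings(eeg_record(data, meta$fs, meta$channel_labels, mask,
                              meta$participant_id, meta$cohort, meta$state))
}

#' Minimal EDF export
#'
#' Standard EDF: 16-bit samples, one data record per second. Data are scaled
#' to the per-channel physical range; the recording is truncated to a whole
#' number of seconds. Artifact masks are not representable in plain EDF and
#' are dropped.
#'
#' @param record an \code{eeg_record} with integer fs.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_edf <- function(record, path) {
  fs <- record$fs
  if (fs != round(fs)) stop("write_edf: integer sampling rate required")
  nch <- nrow(record$data)
  nrec <- floor(ncol(record$data) / fs)
  if (nrec < 1) stop("write_edf: record shorter than one second")
  X <- record$data[, seq_len(nrec * fs), drop = FALSE]
  pmin_ <- apply(X, 1, min); pmax_ <- apply(X, 1, max)
  span <- pmax_ - pmin_
  span[span == 0] <- 1
  pad <- function(s, w) formatC(substr(s, 1, w), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad(record$participant_id, 80),
                pad(paste("cohort", record$cohort, "state", record$state), 80),
                pad("01.01.20", 8), pad("00.00.00", 8),
                pad(as.character(256 * (nch + 1)), 8), pad("", 44),
                pad(as.character(nrec), 8), pad("1", 8),
                pad(as.character(nch), 4))
  writeChar(hdr, con, eos = NULL)
  wfield <- function(vals, w)
    writeChar(paste0(vapply(vals, pad, character(1), w = w), collapse = ""),
              con, eos = NULL)
  wfield(record$channel_labels, 16)
  wfield(rep("synthetic EEG", nch), 80)
  wfield(rep("uV", nch), 8)
  wfield(formatC(pmin_, format = "g", digits = 6), 8)
  wfield(formatC(pmax_, format = "g", digits = 6), 8)
  wfield(rep("-32768", nch), 8)
  wfield(rep("32767", nch), 8)
  wfield(rep("", nch), 80)
  wfield(rep(as.character(fs), nch), 8)
  wfield(rep("", nch), 32)
  for (r in seq_len(nrec)) {
    for (ch in seq_len(nch)) {
      seg <- X[ch, ((r - 1) * fs + 1):(r * fs)]
      dig <- round((seg - pmin_[ch]) / span[ch] * 65535 - 32768)
      writeBin(as.integer(pmax(-32768, pmin(32767, dig))), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Minimal EDF reader
#'
#' Parses the standard EDF header and 16-bit data records, rescales to
#' physical units, and maps labels onto the canonical 19-channel 10-20 order
#' when all 19 are present (with T7/T8/P7/P8 aliases). Requires a uniform
#' sampling rate across signals.
#'
#' @param path EDF file path.
#' @return an \code{eeg_record} (mask all-usable).
#' @export
read_edf <- function(path) {
  if (!grepl("\\.edf$", tolower(path))) stop("read_edf: expected a .edf file")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    s <- readChar(con, w, useBytes = TRUE)
    if (nchar(s, type = "bytes") < w)
      stop("read_edf: truncated header at offset ", seek(con))
    trimws(s)
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  nbytes <- as.integer(rd(8)); rd(44)
  nrec <- as.integer(rd(8)); dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  if (!is.finite(nch) || nch < 1 || !is.finite(nrec))
    stop("read_edf: malformed header at offset 252")
  fld <- function(w) vapply(seq_len(nch), function(i) rd(w), character(1))
  labels <- fld(16); fld(80); fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin_ <- as.numeric(fld(8)); dmax_ <- as.numeric(fld(8))
  fld(80)
  nsamp <- as.integer(fld(8)); fld(32)
  if (length(unique(nsamp)) != 1)
    stop("read_edf: mixed per-signal sampling rates are not supported")
  fs <- nsamp[1] / dur
  X <- matrix(0, nch, nrec * nsamp[1])
  for (r in seq_len(nrec)) {
    for (ch in seq_len(nch)) {
      v <- readBin(con, "integer", n = nsamp[1], size = 2, endian = "little",
                   signed = TRUE)
      if (length(v) < nsamp[1])
        stop("read_edf: truncated data record ", r, " at offset ", seek(con))
      phys <- pmin_[ch] + (v - dmin_[ch]) / (dmax_[ch] - dmin_[ch]) *
        (pmax_[ch] - pmin_[ch])
      X[ch, ((r - 1) * nsamp[1] + 1):(r * nsamp[1])] <- phys
    }
  }
  idx <- match_channels(labels)
  if (!anyNA(idx)) {
    X <- X[idx, , drop = FALSE]
    labels <- channel_order_1020()
  }
  suppressWarnings(eeg_record(X, fs, channel_labels = labels))
}

#' Read a recording in either supported format
#'
#' @param path file path.
#' @param format \code{"fixture"} or \code{"EDF"}; inferred from the
#'   extension by default.
#' @return an \code{eeg_record}.
#' @export
read_recording <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.bin$", path)) "fixture"
              else if (grepl("\\.edf$", tolower(path))) "EDF"
              else stop("read_recording: unrecognized extension for ", path)
  }
  switch(format, fixture = read_fixture(path), EDF = read_edf(path),
         stop("read_recording: unknown format ", format))
}
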