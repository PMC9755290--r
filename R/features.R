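#' Canonical feature catalogue
#'
#' The 42 channel- or pair-averaged features, grouped into five categories:
#' scEntropy (mMSE, LZ, CTW, PermEn at 5 lags), fcEntropy (short- and
#' long-range wSMI at 5 lags), scSpectralA / scSpectralR (absolute and
#' relative power in 6 bands), fcSpectral (short- and long-range dwPLI in
#' 6 bands).
#'
#' @return data.frame with columns \code{name} and \code{category}.
#' @export
canonical_features <- function() {
  taus <- c(8, 16, 32, 64, 128)
  bands <- names(band_set())
  rbind(
    data.frame(name = c("mMSE", "LZ", "CTW", paste0("PermEn", taus)),
               category = "scEntropy"),
    data.frame(name = c(paste0("SRwSMI", taus), paste0("LRwSMI", taus)),
               category = "fcEntropy"),
    data.frame(name = paste0(bands, "A"), category = "scSpectralA"),
    data.frame(name = paste0(bands, "R"), category = "scSpectralR"),
    data.frame(name = c(paste0("SRdwPLI", bands), paste0("LRdwPLI", bands)),
               category = "fcSpectral")
  )
}

#' Channel aggregation for single-channel features
#'
#' Global mean across channels; missing channels are averaged over and
#' flagged.
#'
#' @param values numeric vector, one value per channel.
#' @return list with \code{value} and \code{flag_missing}.
#' @export
aggregate_sc <- function(values) {
  list(value = mean(values, na.rm = TRUE), flag_missing = anyNA(values))
}

#' Pair-class aggregation for connectivity features
#'
#' Separate means over short-range and long-range pairs; excluded (< 80 mm)
#' pairs never contribute.
#'
#' @param values numeric vector, one value per pair row.
#' @param classes character vector of pair classes aligned with
#'   \code{values}.
#' @return named vector \code{c(SR = ..., LR = ...)}.
#' @export
aggregate_fc <- function(values, classes) {
  c(SR = mean(values[classes == "short"], na.rm = TRUE),
    LR = mean(values[classes == "long"], na.rm = TRUE))
}

#' Options bundle for feature extraction
#'
#' @param taus_ms permutation-entropy / wSMI lags, ms.
#' @param mmse an \code{mmse_config}.
#' @param lzctw an \code{lzctw_config}.
#' @param grid a \code{wavelet_grid}.
#' @param pairs pair table from \code{\link{pair_classification}}.
#' @param categories feature categories to compute.
#' @return list of class \code{feature_opts}.
#' @export
feature_opts <- function(taus_ms = c(8, 16, 32, 64, 128),
                         mmse = mmse_config(), lzctw = lzctw_config(),
                         grid = wavelet_grid(), pairs = NULL,
                         categories = c("scEntropy", "fcEntropy",
                                        "scSpectralA", "scSpectralR",
                                        "fcSpectral")) {
  structure(list(taus_ms = taus_ms, mmse = mmse, lzctw = lzctw, grid = grid,
                 pairs = pairs, categories = categories),
            class = "feature_opts")
}

# all features of one record as a named vector (NA where missing)
extract_features_record <- function(record, opts = feature_opts()) {
  cats <- opts$categories
  cat_names <- canonical_features()
  out <- stats::setNames(rep(NA_real_, nrow(cat_names)), cat_names$name)
  need125 <- any(c("scEntropy", "fcEntropy") %in% cats)
  need200 <- "scEntropy" %in% cats
  if (need200) {
    rec200 <- if (record$fs == opts$lzctw$fs) record
              else downsample(record, opts$lzctw$fs)
  }
  if (need125) rec125 <- if (record$fs == 125) record else downsample(record, 125)
  nch <- nrow(record$data)
  if ("scEntropy" %in% cats) {
    vm <- vl <- vc <- numeric(nch)
    for (ch in seq_len(nch)) {
      x <- rec200$data[ch, ]
      vm[ch] <- mmse(x, opts$mmse, mask = rec200$artifact_mask)$value
      vl[ch] <- lz76(x, opts$lzctw, mask = rec200$artifact_mask)
      vc[ch] <- ctw_entropy_rate(x, opts$lzctw, mask = rec200$artifact_mask)
    }
    out["mMSE"] <- aggregate_sc(vm)$value
    out["LZ"] <- aggregate_sc(vl)$value
    out["CTW"] <- aggregate_sc(vc)$value
    for (tau in opts$taus_ms) {
      vp <- vapply(seq_len(nch), function(ch)
        permen_windowed(rec125$data[ch, ], fs = 125, tau_ms = tau,
                        mask = rec125$artifact_mask), numeric(1))
      out[paste0("PermEn", tau)] <- aggregate_sc(vp)$value
    }
  }
  if (any(c("fcEntropy", "fcSpectral") %in% cats)) {
    pairs <- opts$pairs
    if (is.null(pairs)) pairs <- pair_classification()
  }
  if ("fcEntropy" %in% cats) {
    m <- 3L
    opp <- opposite_symbol_map(m)
    pair_idx <- cbind(pairs$i - 1L, pairs$j - 1L)
    for (tau in opts$taus_ms) {
      tau_s <- as.integer(round(tau * 125 / 1000))
      nsym <- ncol(rec125$data) - (m - 1L) * tau_s
      sym <- matrix(0L, nch, nsym)
      for (ch in seq_len(nch))
        sym[ch, ] <- ordinal_symbols_cpp(rec125$data[ch, ], m, tau_s)
      len <- round(5 * 125); hop <- len %/% 2L
      starts <- clean_window_starts(rec125$artifact_mask, len, hop)
      nsym_w <- len - (m - 1L) * tau_s
      starts <- starts[starts + nsym_w - 1L <= nsym]
      if (length(starts)) {
        v <- wsmi_windows_cpp(sym, pair_idx, starts - 1L,
                              rep(nsym_w, length(starts)), opp,
                              as.integer(factorial(m)))
        pm <- rowMeans(v, na.rm = TRUE)
        ag <- aggregate_fc(pm, pairs$class)
        out[paste0("SRwSMI", tau)] <- ag["SR"]
        out[paste0("LRwSMI", tau)] <- ag["LR"]
      }
    }
  }
  if (any(c("scSpectralA", "scSpectralR") %in% cats)) {
    psd <- morlet_psd(record, opts$grid)
    if ("scSpectralA" %in% cats) {
      bp <- band_power(psd, relative = FALSE)
      out[paste0(colnames(bp), "A")] <- colMeans(bp, na.rm = TRUE)
    }
    if ("scSpectralR" %in% cats) {
      bp <- band_power(psd, relative = TRUE)
      out[paste0(colnames(bp), "R")] <- colMeans(bp, na.rm = TRUE)
    }
  }
  if ("fcSpectral" %in% cats) {
    dw <- dwpli(record, opts$grid, pairs)
    for (b in colnames(dw$pair_band)) {
      ag <- aggregate_fc(dw$pair_band[, b], pairs$class)
      out[paste0("SRdwPLI", b)] <- ag["SR"]
      out[paste0("LRdwPLI", b)] <- ag["LR"]
    }
  }
  keep <- cat_names$category %in% cats
  # lag-indexed features exist only for the requested lags
  tau_feats <- grep("^(PermEn|SRwSMI|LRwSMI)", cat_names$name, value = TRUE)
  wanted <- c(setdiff(cat_names$name, tau_feats),
              paste0("PermEn", opts$taus_ms),
              paste0("SRwSMI", opts$taus_ms), paste0("LRwSMI", opts$taus_ms))
  out[keep & cat_names$name %in% wanted]
}

#' Build the recording-by-feature table
#'
#' One row per recording-state with metadata columns (participant_id, cohort,
#' state, usable_length_s) followed by the channel-/pair-averaged features.
#'
#' @param records list of \code{eeg_record}s.
#' @param opts a \code{feature_opts}.
#' @param preprocess logical; apply \code{\link{bandpass}} and
#'   \code{\link{average_reference}} first.
#' @param progress logical; print one line per record.
#' @return data.frame of class \code{feature_table}.
#' @export
feature_table <- function(records, opts = feature_opts(), preprocess = TRUE,
                          progress = FALSE) {
  rows <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    if (progress)
      message(sprintf("features: %s %s", rec$participant_id, rec$state))
    if (preprocess) rec <- average_reference(bandpass(rec))
    vals <- extract_features_record(rec, opts)
    rows[[i]] <- data.frame(participant_id = rec$participant_id,
                            cohort = rec$cohort, state = rec$state,
                            usable_length_s = usable_length_s(rec),
                            t(vals), check.names = FALSE,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("feature_table", "data.frame")
  out
}

feature_columns <- function(table) {
  setdiff(colnames(table),
          c("participant_id", "cohort", "state", "usable_length_s"))
}
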