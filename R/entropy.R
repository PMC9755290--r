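#' Configuration for multiscale fuzzy sample entropy
#'
#' Coarse-grained sample entropy with a sigmoidal neighbour-membership
#' function. Signals are analysed at 200 Hz in nonoverlapping 30 s segments;
#' the state-space radius is 0.15 of the (per-scale, recomputed) SD; scales
#' 1-20 are computed and the first 10 averaged into the reported value.
#'
#' @param scales integer scales (coarse-graining block sizes).
#' @param average_scales scales entering the reported average.
#' @param r_factor radius as a fraction of the coarse-grained SD.
#' @param segment_s segment length, seconds (nonoverlapping).
#' @param fs analysis sampling rate, Hz.
#' @param min_valid_samples minimum coarse-grained samples per scale.
#' @param m embedding dimension.
#' @param max_segments cap on the number of segments used (runtime control).
#' @return list of class \code{mmse_config}.
#' @export
mmse_config <- function(scales = 1:20, average_scales = 1:10, r_factor = 0.15,
                        segment_s = 30, fs = 200, min_valid_samples = 100,
                        m = 2, max_segments = Inf) {
  stopifnot(all(scales >= 1), r_factor > 0)
  structure(list(scales = as.integer(scales),
                 average_scales = as.integer(average_scales),
                 r_factor = r_factor, segment_s = segment_s, fs = fs,
                 min_valid_samples = min_valid_samples, m = as.integer(m),
                 max_segments = max_segments),
            class = "mmse_config")
}

#' Configuration for Lempel-Ziv-76 and CTW entropy rate
#'
#' Median-binarized signals at 200 Hz in nonoverlapping 60 s segments;
#' segments need at least 2000 usable samples (a trailing partial segment is
#' kept when it meets that minimum).
#'
#' @param segment_s segment length, seconds.
#' @param fs analysis sampling rate, Hz.
#' @param min_samples minimum usable samples per segment.
#' @param depth CTW context-tree depth.
#' @param max_segments cap on the number of segments used.
#' @return list of class \code{lzctw_config}.
#' @export
lzctw_config <- function(segment_s = 60, fs = 200, min_samples = 2000,
                         depth = 20, max_segments = Inf) {
  if (min_samples > segment_s * fs)
    stop("lzctw_config: min_samples exceeds the segment length")
  structure(list(segment_s = segment_s, fs = fs, min_samples = min_samples,
                 depth = as.integer(depth), max_segments = max_segments),
            class = "lzctw_config")
}

#' Ordinal-pattern symbolization
#'
#' Maps each embedded window (x_t, x_{t+tau}, ..., m samples) to the index of
#' its rank permutation; ties are broken by temporal order (the earlier sample
#' ranks lower).
#'
#' @param signal numeric vector.
#' @param m embedding dimension (alphabet size m!).
#' @param tau_samples sample lag between embedded points.
#' @return object of class \code{symbolic_series}: \code{symbols} (0-based),
#'   \code{m}, \code{tau_samples}, and \code{opposite_map} giving, for each
#'   symbol, the symbol of the sign-flipped pattern.
#' @export
ordinal_symbolize <- function(signal, m = 3, tau_samples = 1) {
  n <- length(signal)
  if (n <= (m - 1) * tau_samples)
    stop("ordinal_symbolize: signal too short for m = ", m,
         ", tau = ", tau_samples)
  sym <- ordinal_symbols_cpp(as.numeric(signal), as.integer(m),
                             as.integer(tau_samples))
  structure(list(symbols = sym, m = as.integer(m),
                 tau_samples = as.integer(tau_samples),
                 opposite_map = opposite_symbol_map(m)),
            class = "symbolic_series")
}

# permutations of 0..m-1 in lexicographic order (rows = symbols)
rank_patterns <- function(m) {
  perms <- function(v) {
    if (length(v) == 1) return(matrix(v, 1))
    out <- NULL
    for (i in seq_along(v))
      out <- rbind(out, cbind(v[i], perms(v[-i])))
    out
  }
  perms(0:(m - 1))
}

# symbol -> symbol of the time pattern with all values negated
opposite_symbol_map <- function(m) {
  pats <- rank_patterns(m)
  key <- apply(pats, 1, paste, collapse = ",")
  opp <- apply(pats, 1, function(r) paste((m - 1) - r, collapse = ","))
  match(opp, key) - 1L
}

#' Normalized permutation entropy of a symbol stream
#'
#' Shannon entropy of the ordinal-pattern distribution divided by ln(m!), so
#' the value lies in [0, 1]: 0 for a single repeated pattern, 1 for the
#' uniform pattern distribution.
#'
#' @param series a \code{symbolic_series}, or an integer vector of 0-based
#'   symbols (then \code{m} must be given).
#' @param m embedding dimension when \code{series} is a bare vector.
#' @return normalized permutation entropy in [0, 1].
#' @export
perm_entropy <- function(series, m = NULL) {
  if (inherits(series, "symbolic_series")) {
    sym <- series$symbols; m <- series$m
  } else {
    if (is.null(m)) stop("perm_entropy: m required for a bare symbol vector")
    sym <- series
  }
  if (length(sym) < 1) return(NA_real_)
  counts <- tabulate(sym + 1L, nbins = factorial(m))
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p)) / log(factorial(m))
}

# usable analysis windows: start indices (1-based) of length `len` windows at
# hop `hop` that contain no masked sample
clean_window_starts <- function(mask, len, hop) {
  n <- length(mask)
  if (n < len) return(integer(0))
  starts <- seq(1L, n - len + 1L, by = hop)
  cm <- c(0, cumsum(!mask))
  starts[(cm[starts + len] - cm[starts]) == 0]
}

#' Windowed permutation entropy of a single channel
#'
#' The recording-level convention: symbols at lag \code{tau_ms} on data
#' downsampled to 125 Hz, entropy per 5 s window with 50% overlap, windows
#' overlapping masked samples dropped, remaining windows averaged.
#'
#' @param signal numeric vector (already at \code{fs}).
#' @param fs sampling rate, Hz (the convention is 125).
#' @param tau_ms lag in milliseconds (8, 16, 32, 64 or 128 at 125 Hz).
#' @param m embedding dimension.
#' @param window_s window length, seconds.
#' @param overlap window overlap fraction.
#' @param mask logical usable-sample mask.
#' @return mean windowed permutation entropy, or \code{NA} if no valid window.
#' @export
permen_windowed <- function(signal, fs = 125, tau_ms = 32, m = 3,
                            window_s = 5, overlap = 0.5, mask = NULL) {
  tau <- tau_ms * fs / 1000
  if (abs(tau - round(tau)) > 1e-9)
    stop("permen_windowed: tau_ms * fs must give an integer sample lag")
  tau <- as.integer(round(tau))
  n <- length(signal)
  if (is.null(mask)) mask <- rep(TRUE, n)
  len <- round(window_s * fs)
  hop <- max(1L, round(len * (1 - overlap)))
  starts <- clean_window_starts(mask, len, hop)
  nsym_w <- len - (m - 1L) * tau
  if (nsym_w < 1) stop("permen_windowed: window too short for the lag")
  if (!length(starts)) return(NA_real_)
  sym <- ordinal_symbols_cpp(as.numeric(signal), as.integer(m), tau)
  vals <- vapply(starts, function(s) {
    idx <- s:(s + nsym_w - 1L)
    idx <- idx[idx <= length(sym)]
    perm_entropy(sym[idx], m = m)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Weighted symbolic mutual information between two symbol streams
#'
#' Mutual information of the joint ordinal-pattern distribution with pairs of
#' identical or sign-opposite symbols zero-weighted (suppressing
#' volume-conduction artifacts), normalized by the two local permutation
#' entropies:
#' \deqn{wSMI'(X,Y) = 2\, wSMI(X,Y) / (PE(X) + PE(Y))}
#' where PE terms are unnormalized natural-log entropies (so numerator and
#' denominator share units). Computed per window and averaged when windowing
#' parameters are given.
#'
#' @param series_x,series_y \code{symbolic_series} with identical (m, tau).
#' @param fs sampling rate of the underlying signal, Hz; when supplied
#'   together with \code{window_s}, values are computed in windows of the
#'   underlying samples with the given overlap and averaged.
#' @param window_s,overlap windowing of the underlying signal (NULL = one
#'   window over the whole stream).
#' @param mask usable-sample mask of the underlying signal.
#' @return normalized wSMI value (\code{NA} if no valid window or degenerate
#'   entropies).
#' @export
wsmi <- function(series_x, series_y, fs = NULL, window_s = NULL,
                 overlap = 0.5, mask = NULL) {
  stopifnot(inherits(series_x, "symbolic_series"),
            inherits(series_y, "symbolic_series"))
  if (series_x$m != series_y$m || series_x$tau_samples != series_y$tau_samples)
    stop("wsmi: series must share (m, tau)")
  nx <- length(series_x$symbols); ny <- length(series_y$symbols)
  if (nx != ny) stop("wsmi: series must be aligned (equal length)")
  m <- series_x$m
  sym <- rbind(series_x$symbols, series_y$symbols)
  if (is.null(window_s) || is.null(fs)) {
    w_start <- 0L; w_len <- nx
  } else {
    tau <- series_x$tau_samples
    len <- round(window_s * fs)
    hop <- max(1L, round(len * (1 - overlap)))
    n_sig <- nx + (m - 1L) * tau
    if (is.null(mask)) mask <- rep(TRUE, n_sig)
    starts <- clean_window_starts(mask, len, hop)
    nsym_w <- len - (m - 1L) * tau
    starts <- starts[starts + nsym_w - 1L <= nx]
    if (!length(starts)) return(NA_real_)
    w_start <- starts - 1L; w_len <- rep(nsym_w, length(starts))
  }
  v <- wsmi_windows_cpp(sym, matrix(c(0L, 1L), 1), as.integer(w_start),
                        as.integer(w_len), series_x$opposite_map,
                        as.integer(factorial(m)))
  if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
}

#' Multiscale fuzzy sample entropy (mMSE)
#'
#' Per nonoverlapping segment and scale s, the signal (usable samples only)
#' is coarse-grained by averaging blocks of s samples, standardized, and the
#' sample entropy computed with a sigmoidal membership
#' \eqn{\mu(d) = 1/(1+\exp((d-0.5)/r))} in place of the hard threshold, with
#' \eqn{r = 0.15 \times SD} of the (per-scale) coarse-grained series.
#' Scale values are averaged across segments; the reported value averages
#' scales 1-10.
#'
#' @param signal numeric vector at \code{config$fs}.
#' @param config an \code{mmse_config}.
#' @param mask usable-sample mask.
#' @return list with \code{per_scale} (named vector over scales) and
#'   \code{value} (mean over \code{average_scales}); \code{value} is \code{NA}
#'   for degenerate (constant) input or when no segment-scale is valid.
#' @export
mmse <- function(signal, config = mmse_config(), mask = NULL) {
  n <- length(signal)
  if (is.null(mask)) mask <- rep(TRUE, n)
  seg_len <- round(config$segment_s * config$fs)
  bounds <- segment_bounds(n, seg_len, config$max_segments)
  per_scale <- matrix(NA_real_, length(config$scales), nrow(bounds))
  for (g in seq_len(nrow(bounds))) {
    seg <- signal[bounds[g, 1]:bounds[g, 2]]
    segmask <- mask[bounds[g, 1]:bounds[g, 2]]
    x <- seg[segmask]
    if (length(x) < 2 || stats::sd(x) == 0) next
    for (si in seq_along(config$scales)) {
      s <- config$scales[si]
      nb <- length(x) %/% s
      if (nb < config$min_valid_samples) next
      cg <- colMeans(matrix(x[seq_len(nb * s)], nrow = s))
      sdc <- stats::sd(cg)
      if (!is.finite(sdc) || sdc == 0) next
      cg <- (cg - mean(cg)) / sdc
      r <- config$r_factor * stats::sd(cg)
      cnt <- fuzzy_sampen_counts_cpp(cg, config$m, r)
      if (cnt[1] > 0 && cnt[2] > 0)
        per_scale[si, g] <- -log(cnt[2] / cnt[1])
    }
  }
  ps <- rowMeans(per_scale, na.rm = TRUE)
  ps[is.nan(ps)] <- NA_real_
  names(ps) <- config$scales
  avg_idx <- match(config$average_scales, config$scales)
  vals <- ps[avg_idx[!is.na(avg_idx)]]
  value <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  list(per_scale = ps, value = value)
}

# nonoverlapping segment bounds (1-based, inclusive); the trailing partial
# segment is kept (callers enforce their own minimum-sample rules)
segment_bounds <- function(n, seg_len, max_segments = Inf) {
  starts <- seq(1L, n, by = seg_len)
  ends <- pmin(starts + seg_len - 1L, n)
  keep <- seq_len(min(length(starts), max_segments))
  cbind(starts[keep], ends[keep])
}

#' Normalized Lempel-Ziv-76 complexity
#'
#' Per segment: usable samples are binarized at their median, the number of
#' exhaustive-history phrases c is counted, and c is normalized by
#' N / log2(N). Segment values are averaged.
#'
#' @param signal numeric vector at \code{config$fs}.
#' @param config an \code{lzctw_config}.
#' @param mask usable-sample mask.
#' @return normalized complexity (\code{NA} when every segment is dropped).
#' @export
lz76 <- function(signal, config = lzctw_config(), mask = NULL) {
  vals <- binary_segment_apply(signal, config, mask, function(b) {
    N <- length(b)
    lz76_count_cpp(b) / (N / log2(N))
  })
  if (!length(vals)) NA_real_ else mean(vals)
}

#' Context-tree-weighting entropy rate
#'
#' Per segment: usable samples are binarized at their median and the entropy
#' rate (bits per symbol) estimated by context-tree weighting with the
#' Krichevsky-Trofimov estimator at every node. Segment values are averaged.
#'
#' @param signal numeric vector at \code{config$fs}.
#' @param config an \code{lzctw_config}.
#' @param depth context-tree depth (defaults to the config's).
#' @param mask usable-sample mask.
#' @return entropy rate in bits per symbol (\code{NA} when every segment is
#'   dropped).
#' @export
ctw_entropy_rate <- function(signal, config = lzctw_config(), depth = NULL,
                             mask = NULL) {
  if (is.null(depth)) depth <- config$depth
  vals <- binary_segment_apply(signal, config, mask, function(b) {
    ctw_rate_cpp(b, as.integer(depth))
  })
  if (!length(vals)) NA_real_ else mean(vals)
}

binary_segment_apply <- function(signal, config, mask, fn) {
  n <- length(signal)
  if (is.null(mask)) mask <- rep(TRUE, n)
  seg_len <- round(config$segment_s * config$fs)
  bounds <- segment_bounds(n, seg_len, config$max_segments)
  out <- numeric(0)
  for (g in seq_len(nrow(bounds))) {
    x <- signal[bounds[g, 1]:bounds[g, 2]]
    x <- x[mask[bounds[g, 1]:bounds[g, 2]]]
    if (length(x) < config$min_samples) next
    b <- as.integer(x > stats::median(x))
    out <- c(out, fn(b))
  }
  out
}
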