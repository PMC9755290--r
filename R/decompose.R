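#' Phase-randomized surrogate of a segment
#'
#' Replaces the phases of all positive-frequency bins with i.i.d. uniform
#' draws (DC and Nyquist kept real) and inverse-transforms; the amplitude
#' spectrum is preserved exactly and the output is real.
#'
#' @param segment real-valued numeric vector.
#' @param seed optional integer seed; by default the current RNG stream is
#'   consumed.
#' @return surrogate segment.
#' @export
phase_randomize <- function(segment, seed = NULL) {
  if (!is.null(seed)) set.seed(seed %% 2000000011)
  n <- length(segment)
  nh <- (n - 1) %/% 2
  X <- stats::fft(segment)
  if (nh >= 1) {
    idx <- 2:(nh + 1)
    X[idx] <- Mod(X[idx]) * exp(1i * stats::runif(nh, 0, 2 * pi))
    X[n + 2 - idx] <- Conj(X[idx])
  }
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Cross-condition phase-swap surrogate
#'
#' Combines the amplitude spectrum of one segment with the phases of a donor
#' segment (equal lengths required); DC and Nyquist magnitudes keep the
#' amplitude segment's values with the donor's signs.
#'
#' @param segment_amp segment supplying amplitudes.
#' @param segment_phase donor segment supplying phases.
#' @return surrogate segment with \code{segment_amp}'s amplitude spectrum.
#' @export
phase_swap <- function(segment_amp, segment_phase) {
  n <- length(segment_amp)
  if (length(segment_phase) != n)
    stop("phase_swap: segments must have equal length")
  A <- stats::fft(segment_amp)
  B <- stats::fft(segment_phase)
  X <- Mod(A) * exp(1i * Arg(B))
  # enforce conjugate symmetry exactly (guards against rounding)
  X[1] <- Mod(A[1]) * sign(Re(B[1]) + (Re(B[1]) == 0))
  if (n %% 2 == 0) {
    k <- n / 2 + 1
    X[k] <- Mod(A[k]) * sign(Re(B[k]) + (Re(B[k]) == 0))
  }
  nh <- (n - 1) %/% 2
  if (nh >= 1) X[n + 2 - (2:(nh + 1))] <- Conj(X[2:(nh + 1)])
  Re(stats::fft(X, inverse = TRUE)) / n
}

# normalized PermEn of one segment (whole segment as a single window)
segment_permen <- function(x, m, tau_samples) {
  perm_entropy(ordinal_symbolize(x, m = m, tau_samples = tau_samples))
}

#' Surrogate decomposition of the wake-sleep permutation-entropy change
#'
#' Partitions delta PermEn (wake minus sleep) into amplitude, phase and
#' interaction terms using phase surrogates on balanced segment sets:
#' \itemize{
#'   \item amplitude: the PermEn gap that survives within-condition phase
#'     randomization (only the amplitude spectra still differ);
#'   \item phase: the gap attributable to condition-specific phase
#'     distributions, estimated by transplanting wake versus sleep phases
#'     onto a common amplitude background (averaged over both backgrounds,
#'     one random donor segment per surrogate);
#'   \item interaction: the residual, so the three terms sum to the total
#'     exactly.
#' }
#' The non-amplitude term is phase + interaction.
#'
#' @param wake_segments,sleep_segments lists (or matrices, rows = segments)
#'   of equal-length segments, balanced counts.
#' @param taus_ms PermEn lags, ms.
#' @param n_surrogates surrogates per term.
#' @param fs segment sampling rate, Hz.
#' @param m embedding dimension.
#' @param seed integer seed.
#' @return data.frame of class \code{decomp_components}: tau_ms, term
#'   (total, amplitude, phase, interaction, non_amplitude), value, mc_se
#'   (surrogate Monte-Carlo standard error; NA for the deterministic total).
#' @export
decompose_permen <- function(wake_segments, sleep_segments,
                             taus_ms = c(8, 16, 32, 64, 128),
                             n_surrogates = 1000, fs = 125, m = 3, seed = 1) {
  as_list <- function(x) {
    if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) x[i, ]) else x
  }
  W <- as_list(wake_segments); S <- as_list(sleep_segments)
  if (length(W) != length(S))
    stop("decompose_permen: segment counts must be balanced between conditions")
  nseg <- length(W)
  if (nseg < 1) stop("decompose_permen: no segments")
  set.seed(seed %% 2000000011)
  out <- list()
  for (tau_ms in taus_ms) {
    tau <- as.integer(round(tau_ms * fs / 1000))
    if (tau < 1) stop("decompose_permen: tau below one sample at fs = ", fs)
    peW <- vapply(W, segment_permen, numeric(1), m = m, tau_samples = tau)
    peS <- vapply(S, segment_permen, numeric(1), m = m, tau_samples = tau)
    total <- mean(peW) - mean(peS)
    amp_s <- phase_s <- numeric(n_surrogates)
    for (b in seq_len(n_surrogates)) {
      i <- sample.int(nseg, 1)
      dW <- sample.int(nseg, 1); dS <- sample.int(nseg, 1)
      pe <- function(x) segment_permen(x, m, tau)
      amp_s[b] <- pe(phase_randomize(W[[i]])) - pe(phase_randomize(S[[i]]))
      phase_s[b] <- 0.5 *
        ((pe(phase_swap(W[[i]], W[[dW]])) - pe(phase_swap(W[[i]], S[[dS]]))) +
         (pe(phase_swap(S[[i]], W[[dW]])) - pe(phase_swap(S[[i]], S[[dS]]))))
    }
    amp <- mean(amp_s); ph <- mean(phase_s)
    inter <- total - amp - ph
    se_a <- stats::sd(amp_s) / sqrt(n_surrogates)
    se_p <- stats::sd(phase_s) / sqrt(n_surrogates)
    out[[length(out) + 1]] <- data.frame(
      tau_ms = tau_ms,
      term = c("total", "amplitude", "phase", "interaction", "non_amplitude"),
      value = c(total, amp, ph, inter, ph + inter),
      mc_se = c(NA, se_a, se_p, sqrt(se_a ^ 2 + se_p ^ 2),
                sqrt(se_a ^ 2 + se_p ^ 2)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("decomp_components", "data.frame")
  res
}

#' Draw balanced 5 s segments from a record channel
#'
#' Segments are drawn without replacement from the usable 5 s windows of a
#' channel (50% overlap permitted between candidate windows).
#'
#' @param record an \code{eeg_record} (125 Hz conventional).
#' @param channel channel index.
#' @param n_segments number of segments to draw.
#' @param segment_ms segment length, ms.
#' @return list of numeric segments (error if too few usable windows).
#' @export
draw_segments <- function(record, channel = 1, n_segments = 20,
                          segment_ms = 5000) {
  len <- round(segment_ms / 1000 * record$fs)
  starts <- clean_window_starts(record$artifact_mask, len, max(1L, len %/% 2L))
  if (length(starts) < n_segments)
    stop(sprintf("draw_segments: only %d usable %g ms windows (need %d)",
                 length(starts), segment_ms, n_segments))
  take <- sample(starts, n_segments)
  lapply(take, function(s) record$data[channel, s:(s + len - 1L)])
}

#' Mixed-model contrast of amplitude versus non-amplitude components
#'
#' Per tau, fits \code{value ~ component + (1 | participant)} on the
#' participant-level amplitude and non-amplitude components, with a
#' likelihood-ratio p-value, Benjamini-Hochberg correction across taus, and
#' a paired Cohen's d (mean within-participant difference over the SD of
#' those differences; positive d = non-amplitude exceeds amplitude).
#'
#' @param components data.frame with columns participant_id, tau_ms, term,
#'   value (one amplitude and one non_amplitude row per participant and tau).
#' @param q FDR level.
#' @return data.frame: tau_ms, beta, p, p_fdr, significant, cohens_d.
#' @export
component_stats <- function(components, q = 0.05) {
  cmp <- components[components$term %in% c("amplitude", "non_amplitude"), ]
  if (length(unique(cmp$participant_id)) < 3)
    stop("component_stats: need at least 3 participants")
  taus <- sort(unique(cmp$tau_ms))
  res <- data.frame(tau_ms = taus, beta = NA_real_, p = NA_real_,
                    cohens_d = NA_real_)
  for (i in seq_along(taus)) {
    d <- cmp[cmp$tau_ms == taus[i], ]
    d$comp01 <- as.numeric(d$term == "non_amplitude")
    fit <- tryCatch({
      m1 <- suppressWarnings(suppressMessages(
        lme4::lmer(value ~ comp01 + (1 | participant_id), data = d,
                   REML = FALSE)))
      m0 <- suppressWarnings(suppressMessages(
        lme4::lmer(value ~ 1 + (1 | participant_id), data = d, REML = FALSE)))
      an <- stats::anova(m0, m1)
      list(beta = unname(lme4::fixef(m1)["comp01"]),
           p = an[["Pr(>Chisq)"]][2])
    }, error = function(e) {
      tt <- stats::t.test(d$value[d$comp01 == 1], d$value[d$comp01 == 0],
                          paired = TRUE)
      list(beta = unname(tt$estimate), p = tt$p.value)
    })
    res$beta[i] <- fit$beta
    res$p[i] <- fit$p
    av <- tapply(d$value[d$comp01 == 0], d$participant_id[d$comp01 == 0], mean)
    nv <- tapply(d$value[d$comp01 == 1], d$participant_id[d$comp01 == 1], mean)
    common <- intersect(names(av), names(nv))
    diffs <- nv[common] - av[common]
    res$cohens_d[i] <- mean(diffs) / stats::sd(diffs)
  }
  ok <- is.finite(res$p)
  res$p_fdr <- NA_real_
  res$p_fdr[ok] <- fdr_bh(res$p[ok], q)$p_adjusted
  res$significant <- !is.na(res$p_fdr) & res$p_fdr < q
  res
}
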