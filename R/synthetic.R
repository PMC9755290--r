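#' Seeded 1/f ("pink") noise
#'
#' Spectral synthesis: Fourier magnitudes proportional to f^(-alpha/2) with
#' i.i.d. uniform phases, inverse-transformed and standardized to zero mean
#' and unit sample SD.
#'
#' @param n_samples number of samples (>= 2).
#' @param fs sampling rate, Hz (only fixes the physical frequency axis).
#' @param alpha spectral exponent (0 = white, 2 = brown-ish EEG background).
#' @param seed integer seed; if \code{NULL} the current RNG stream is used.
#' @return numeric vector of length \code{n_samples}.
#' @export
generate_pink_noise <- function(n_samples, fs = 500, alpha = 2, seed = NULL) {
  if (n_samples < 2 || fs <= 0) stop("generate_pink_noise: invalid arguments")
  if (alpha < 0) stop("generate_pink_noise: alpha must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_samples)
  nh <- n %/% 2
  f <- (1:nh) * fs / n
  mag <- f ^ (-alpha / 2)
  ph <- stats::runif(nh, 0, 2 * pi)
  X <- complex(n)
  X[2:(nh + 1)] <- mag * exp(1i * ph)
  if (n %% 2 == 0) X[nh + 1] <- Re(X[nh + 1])  # Nyquist bin real
  X[n:(n - nh + 2)] <- Conj(X[2:nh])
  x <- Re(stats::fft(X, inverse = TRUE))
  as.numeric(scale(x))
}

#' Cohort configuration for the synthetic-EEG generator
#'
#' Encodes one oscillatory regime of the testbed:
#' \describe{
#'   \item{AS_like}{dominant 2-4 Hz power in both wake and sleep (the
#'     high-amplitude delta phenotype that dissociates slow waves from
#'     unconsciousness).}
#'   \item{NT_like}{an 8-16 Hz peak awake and slower (1-4 Hz) activity in
#'     sleep, the typical developmental pattern.}
#'   \item{DUP_like}{dominant 16-32 Hz beta power in both states.}
#' }
#' In every regime the wake signal is a partially phase-randomized surrogate
#' of a phase-structured template, so wakefulness carries higher temporal
#' complexity than sleep at a matched (for AS/DUP identical) amplitude
#' spectrum. \code{complexity_gap} is the fraction of structured Fourier bins
#' whose phases are randomized in wake relative to sleep.
#'
#' @param regime one of \code{"AS_like"}, \code{"NT_like"}, \code{"DUP_like"}.
#' @param n_participants participants in the cohort.
#' @param n_channels number of channels (19-channel 10-20 montage).
#' @param fs sampling rate, Hz.
#' @param duration_s seconds of data per state.
#' @param dominant_band named list \code{wake}/\code{nrem} of (lo, hi) Hz; the
#'   regime default is used when \code{NULL}. AS_like and DUP_like must use the
#'   same band in both states.
#' @param complexity_gap fraction in [0, 1] of phase randomization applied to
#'   wake relative to sleep.
#' @param bg_alpha spectral exponent of the structured 1/f background.
#' @param coupling_lag_ms lag of the shared narrowband source injected into
#'   coupled channel pairs, ms.
#' @param coupling_strength amplitude of the lagged source relative to the
#'   channel SD.
#' @param mixing_strength zero-lag volume-conduction mixing in [0, 1).
#' @param amplitude_uv overall signal scale, microvolts (SD); regime default
#'   when \code{NULL}.
#' @param mask_fraction fraction of samples covered by synthetic artifact
#'   intervals (mask exercising only; no artifact waveforms are simulated).
#' @param seed integer seed for participant-level structure.
#' @return list of class \code{cohort_config}.
#' @export
cohort_config <- function(regime = c("AS_like", "NT_like", "DUP_like"),
                          n_participants = 10, n_channels = 19, fs = 200,
                          duration_s = 300, dominant_band = NULL,
                          complexity_gap = 0.85, bg_alpha = 1.2,
                          coupling_lag_ms = 20,
                          coupling_strength = 0.35, mixing_strength = 0.25,
                          amplitude_uv = NULL, mask_fraction = 0.05,
                          seed = 1) {
  regime <- match.arg(regime)
  if (complexity_gap < 0 || complexity_gap > 1)
    stop("cohort_config: complexity_gap must be in [0, 1]")
  if (mixing_strength < 0 || mixing_strength >= 1)
    stop("cohort_config: mixing_strength must be in [0, 1)")
  defaults <- switch(regime,
    AS_like = list(band = list(wake = c(2, 4), nrem = c(2, 4)),
                   amp = 100, osc = 2.5),
    NT_like = list(band = list(wake = c(8, 16), nrem = c(1, 4)),
                   amp = 30, osc = 1.3),
    DUP_like = list(band = list(wake = c(16, 32), nrem = c(16, 32)),
                    amp = 40, osc = 0.8))
  if (is.null(dominant_band)) dominant_band <- defaults$band
  if (regime %in% c("AS_like", "DUP_like") &&
      !isTRUE(all.equal(dominant_band$wake, dominant_band$nrem)))
    stop("cohort_config: ", regime, " must use the same dominant band in both states")
  if (is.null(amplitude_uv)) amplitude_uv <- defaults$amp
  structure(list(regime = regime, n_participants = as.integer(n_participants),
                 n_channels = as.integer(n_channels), fs = fs,
                 duration_s = duration_s, dominant_band = dominant_band,
                 complexity_gap = complexity_gap, bg_alpha = bg_alpha,
                 coupling_lag_ms = coupling_lag_ms,
                 coupling_strength = coupling_strength,
                 mixing_strength = mixing_strength,
                 osc_ratio = defaults$osc,
                 amplitude_uv = amplitude_uv,
                 mask_fraction = mask_fraction, seed = as.integer(seed)),
            class = "cohort_config")
}

# deterministic small hash of a string into a seed offset
string_seed <- function(s) {
  v <- utf8ToInt(as.character(s))
  as.integer(sum(v * (seq_along(v) %% 31 + 1)) %% 100003L)
}

# Phase-structured template for one state. Two components per channel:
# (1) a low-entropy 1/f background built by Hann overlap-add of short
#     chirplet blocks (pink magnitudes, deterministic quadratic phases with
#     random per-block parameters) -- locally deterministic, hence low
#     temporal complexity, but with no stable cross-window or cross-channel
#     phase relation, so it contributes no lag-consistent connectivity;
# (2) a shared harmonic-stacked oscillation in the dominant band whose phase
#     diffuses independently per channel (keeping the nonsinusoidal waveform
#     and spectral peak while decorrelating channels and windows).
# Columns are channels. Consumes the current RNG stream.
build_template <- function(config, band, n) {
  fs <- config$fs
  nch <- config$n_channels
  # per-channel source frequencies spanning the dominant band: channel
  # averaging then suppresses the frequency-idiosyncratic component of
  # feature levels while the wake-sleep gap is common to all channels
  f0_ch <- stats::runif(nch, band[1], band[2])
  phi1 <- stats::runif(1, 0, 2 * pi)
  gains <- 0.6 + 0.8 * stats::runif(nch)
  t_idx <- (0:(n - 1)) / fs
  # deterministic burst envelope: low-entropy amplitude structure that a
  # phase-randomized surrogate cannot reproduce
  f_env_ch <- stats::runif(nch, 0.6, 1.0)
  phi_env_ch <- stats::runif(nch, 0, 2 * pi)
  # deterministic frequency modulation of the carrier: a predictable sweep
  # within the dominant band whose structure a surrogate cannot reproduce
  f_mod_ch <- stats::runif(nch, 0.5, 1.1)
  mod_depth <- 0.25
  phi_mod_ch <- stats::runif(nch, 0, 2 * pi)
  # phase-diffusion scale: cross-window decorrelation over ~8 s
  step_sd <- pi / sqrt(8 * fs)
  blk <- round(2.5 * fs); hop <- blk %/% 2
  kb <- blk %/% 2
  fb <- (1:kb) * fs / blk
  magb <- fb ^ (-config$bg_alpha / 2)
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(blk - 1)) / blk)  # Hann, 50% COLA
  X <- matrix(0, n, nch)
  for (ch in seq_len(nch)) {
    theta <- cumsum(stats::rnorm(n, 0, step_sd))
    n_harm <- min(max(1, floor(42 / f0_ch[ch])), 4)
    harm_phase <- phi1 * seq_len(n_harm) + 0.3 * (seq_len(n_harm) - 1)
    env <- 0.15 + 0.85 *
      (0.5 + 0.5 * sin(2 * pi * f_env_ch[ch] * t_idx + phi_env_ch[ch])) ^ 2
    inst_f <- f0_ch[ch] *
      (1 + mod_depth * sin(2 * pi * f_mod_ch[ch] * t_idx + phi_mod_ch[ch]))
    carrier <- 2 * pi * cumsum(inst_f) / fs
    osc <- rep(0, n)
    for (h in seq_len(n_harm))
      osc <- osc + h ^ (-1.5) * sin(h * carrier + h * theta + harm_phase[h])
    osc <- osc * env
    osc <- osc / stats::sd(osc)
    bg <- rep(0, n)
    starts <- seq(1L, n, by = hop)
    for (s0 in starts) {
      gam <- stats::runif(1, 10, 40) * sample(c(-1, 1), 1)
      psi <- stats::runif(1, 0, 2 * pi)
      S <- complex(blk)
      S[2:(kb + 1)] <- magb * exp(1i * (psi + 2 * pi * gam * ((1:kb) / kb) ^ 2))
      if (blk %% 2 == 0) S[kb + 1] <- Re(S[kb + 1])
      S[blk:(blk - kb + 2)] <- Conj(S[2:kb])
      chirp <- Re(stats::fft(S, inverse = TRUE))
      chirp <- chirp / stats::sd(chirp)
      e0 <- min(s0 + blk - 1L, n)
      len <- e0 - s0 + 1L
      bg[s0:e0] <- bg[s0:e0] + (win * chirp)[seq_len(len)]
    }
    bg <- bg / stats::sd(bg)
    X[, ch] <- bg + config$osc_ratio * gains[ch] * osc
  }
  X
}

# Randomize the phases of a random fraction of positive-frequency bins;
# amplitude spectrum preserved exactly. Consumes the current RNG stream.
partial_phase_randomize <- function(x, fraction) {
  n <- length(x)
  nh <- n %/% 2
  X <- stats::fft(x)
  pick <- which(stats::runif(nh) < fraction)
  pick <- pick[pick >= 1]
  idx <- pick + 1L                      # positive-frequency bins 2..nh+1
  if (n %% 2 == 0) idx <- idx[idx != nh + 1]  # keep Nyquist real
  if (length(idx)) {
    X[idx] <- Mod(X[idx]) * exp(1i * stats::runif(length(idx), 0, 2 * pi))
    mirror <- n + 2L - idx
    X[mirror] <- Conj(X[idx])
  }
  Re(stats::fft(X, inverse = TRUE)) / n
}

# narrowband noise centred in a band (for lagged coupling sources)
narrowband_noise <- function(n, fs, band, bw = 1.5) {
  nh <- n %/% 2
  f <- (1:nh) * fs / n
  fc <- sqrt(band[1] * band[2])
  mag <- exp(-0.5 * ((f - fc) / bw) ^ 2)
  ph <- stats::runif(nh, 0, 2 * pi)
  X <- complex(n)
  X[2:(nh + 1)] <- mag * exp(1i * ph)
  if (n %% 2 == 0) X[nh + 1] <- Re(X[nh + 1])
  X[n:(n - nh + 2)] <- Conj(X[2:nh])
  x <- Re(stats::fft(X, inverse = TRUE))
  x / stats::sd(x)
}

# channel pairs receiving the lagged shared source (montage indices)
coupled_pairs <- function(nch) {
  p <- cbind(c(1, 3, 4, 9, 14, 18), c(9, 15, 16, 19, 17, 6))
  p[p[, 1] <= nch & p[, 2] <= nch, , drop = FALSE]
}

#' Generate one synthetic EEG recording
#'
#' Construction, in order: (1) a phase-structured template for the state's
#' dominant band (participant-level seed, so AS-/DUP-like wake and sleep share
#' one template realization and hence an identical amplitude spectrum);
#' (2) for wake, partial phase randomization of a \code{complexity_gap}
#' fraction of bins (amplitude spectra preserved exactly); (3) a lagged
#' narrowband source added to designated channel pairs; (4) zero-lag
#' volume-conduction mixing; (5) scaling to microvolts and an optional
#' synthetic artifact mask.
#'
#' @param config a \code{cohort_config}.
#' @param participant_id participant identifier (drives the template seed).
#' @param state \code{"wake"} or \code{"nrem"}.
#' @param seed integer seed for the state-level randomness.
#' @return an \code{eeg_record}.
#' @export
generate_recording <- function(config, participant_id, state = c("wake", "nrem"),
                               seed = 1) {
  state <- match.arg(state)
  fs <- config$fs
  n <- round(config$duration_s * fs)
  if (config$duration_s < 10.9)
    stop("generate_recording: duration_s must cover at least one 10.9 s ",
         "low-frequency analysis window (the 0.5 Hz wavelet)")
  band <- config$dominant_band[[if (state == "wake") "wake" else "nrem"]]
  # participant-level stream: template structure shared between states
  set.seed((config$seed * 131L + string_seed(participant_id)) %% 2000000011)
  X <- build_template(config, band, n)
  # state-level stream: surrogate randomization, coupling, mask
  set.seed(seed %% 2000000011)
  if (state == "wake" && config$complexity_gap > 0) {
    for (ch in seq_len(ncol(X)))
      X[, ch] <- partial_phase_randomize(X[, ch], config$complexity_gap)
  }
  prs <- coupled_pairs(config$n_channels)
  lag <- round(config$coupling_lag_ms / 1000 * fs)
  if (config$coupling_strength > 0 && nrow(prs) > 0 && lag >= 1) {
    for (k in seq_len(nrow(prs))) {
      z <- narrowband_noise(n, fs, band)
      zl <- c(z[(n - lag + 1):n], z[1:(n - lag)])  # circular lag
      sdc <- stats::sd(X[, prs[k, 1]])
      X[, prs[k, 1]] <- X[, prs[k, 1]] + config$coupling_strength * sdc * z
      X[, prs[k, 2]] <- X[, prs[k, 2]] + config$coupling_strength * sdc * zl
    }
  }
  if (config$mixing_strength > 0) {
    nch <- ncol(X)
    W <- (1 - config$mixing_strength) * diag(nch) +
      config$mixing_strength * matrix(1 / nch, nch, nch)
    X <- X %*% t(W)
  }
  X <- X / mean(apply(X, 2, stats::sd)) * config$amplitude_uv
  mask <- rep(TRUE, n)
  if (config$mask_fraction > 0) {
    n_int <- 3L
    len <- round(config$mask_fraction * n / n_int)
    if (len >= 1) {
      starts <- sort(sample.int(n - len, n_int))
      mask <- mask_from_intervals(n, lapply(starts, function(s) c(s, s + len)))
    }
  }
  labs <- channel_order_1020()[seq_len(config$n_channels)]
  eeg_record(t(X), fs, channel_labels = labs, artifact_mask = mask,
             participant_id = as.character(participant_id),
             cohort = config$regime, state = state)
}

#' Generate a full synthetic dataset (training + validation cohorts)
#'
#' Deterministic given \code{seed}: per-recording seeds are drawn once from
#' the master seed and recorded in the manifest.
#'
#' @param train_config a \code{cohort_config} for the training regime.
#' @param val_configs list of \code{cohort_config}s for validation regimes.
#' @param seed master integer seed.
#' @return list with \code{records} (list of \code{eeg_record}) and
#'   \code{manifest} (data.frame: recording_id, participant_id, cohort, state,
#'   seed).
#' @export
generate_dataset <- function(train_config, val_configs = list(), seed = 1) {
  configs <- c(list(train_config), val_configs)
  ids <- unlist(lapply(configs, function(cf)
    sprintf("%s_%02d", cf$regime, seq_len(cf$n_participants))))
  if (anyDuplicated(ids)) stop("generate_dataset: duplicate participant ids")
  set.seed(seed %% 2000000011)
  n_rec <- 2L * length(ids)
  rec_seeds <- sample.int(2000000000L, n_rec)
  records <- vector("list", n_rec)
  manifest <- data.frame(recording_id = character(n_rec),
                         participant_id = character(n_rec),
                         cohort = character(n_rec), state = character(n_rec),
                         seed = integer(n_rec), stringsAsFactors = FALSE)
  k <- 0L
  for (cf in configs) {
    for (p in seq_len(cf$n_participants)) {
      pid <- sprintf("%s_%02d", cf$regime, p)
      for (st in c("wake", "nrem")) {
        k <- k + 1L
        records[[k]] <- generate_recording(cf, pid, st, seed = rec_seeds[k])
        manifest[k, ] <- list(paste(pid, st, sep = "_"), pid, cf$regime, st,
                              rec_seeds[k])
      }
    }
  }
  list(records = records, manifest = manifest)
}

#' Entropy-estimate stability as a function of window length
#'
#' Pink-noise validation of the windowing choices: simulated 1/f signals are
#' preprocessed like real data, an entropy feature is computed at each window
#' length of a grid, and for each length the running mean absolute successive
#' difference of the estimate (up to that length) is summarized across
#' signals with a 95% normal CI.
#'
#' @param n_signals number of simulated signals (>= 2).
#' @param feature \code{"lz"}, \code{"ctw"}, \code{"mmse"}, \code{"permen"},
#'   or a function \code{f(signal, fs, window_s)} returning an estimate.
#' @param window_grid window lengths in seconds; defaults to the feature's
#'   convention (2-100 s step 2 for lz/ctw/mmse; 0.5-20 s step 0.5 for permen).
#' @param fs simulated sampling rate, Hz.
#' @param alpha spectral exponent of the simulated signals.
#' @param tau_ms permutation-entropy time lag (permen only).
#' @param duration_s length of each simulated signal; defaults to the largest
#'   window.
#' @param seed integer seed.
#' @return data.frame: window_s, mean_abs_diff, ci_lo, ci_hi (empty when the
#'   grid has fewer than two lengths).
#' @export
window_length_validation <- function(n_signals, feature = "lz",
                                     window_grid = NULL, fs = 500, alpha = 2,
                                     tau_ms = 32, duration_s = NULL, seed = 1) {
  if (n_signals < 2) stop("window_length_validation: n_signals must be >= 2")
  is_fun <- is.function(feature)
  if (!is_fun) {
    feature <- match.arg(feature, c("lz", "ctw", "mmse", "permen"))
    if (is.null(window_grid))
      window_grid <- if (feature == "permen") seq(0.5, 20, 0.5) else seq(2, 100, 2)
  }
  if (is.null(window_grid)) stop("window_length_validation: window_grid required")
  ng <- length(window_grid)
  if (ng < 2)
    return(data.frame(window_s = numeric(0), mean_abs_diff = numeric(0),
                      ci_lo = numeric(0), ci_hi = numeric(0)))
  if (is.null(duration_s)) duration_s <- max(window_grid)
  set.seed(seed %% 2000000011)
  sig_seeds <- sample.int(2000000000L, n_signals)
  target_fs <- if (!is_fun && feature == "permen") 125 else 200
  run_mat <- matrix(NA_real_, n_signals, ng - 1L)
  for (s in seq_len(n_signals)) {
    x <- generate_pink_noise(round(duration_s * fs), fs, alpha, seed = sig_seeds[s])
    rec <- eeg_record(matrix(x, 1), fs, channel_labels = "Cz")
    rec <- suppressWarnings(bandpass(rec))
    rec <- suppressWarnings(downsample(rec, target_fs))
    xs <- rec$data[1, ]
    est <- vapply(window_grid, function(w) {
      if (is_fun) return(feature(xs, target_fs, w))
      switch(feature,
        lz = lz76(xs, lzctw_config(segment_s = w, fs = target_fs,
                                   min_samples = min(2000, round(w * target_fs)))),
        ctw = ctw_entropy_rate(xs, lzctw_config(segment_s = w, fs = target_fs,
                                   min_samples = min(2000, round(w * target_fs)))),
        mmse = mmse(xs, mmse_config(segment_s = w, fs = target_fs,
                                    min_valid_samples = min(100, round(w * target_fs / 2))))$value,
        permen = permen_windowed(xs, fs = target_fs, tau_ms = tau_ms,
                                 window_s = w))
    }, numeric(1))
    d <- abs(diff(est))
    run_mat[s, ] <- cumsum(d) / seq_along(d)
  }
  mu <- colMeans(run_mat)
  se <- apply(run_mat, 2, stats::sd) / sqrt(n_signals)
  data.frame(window_s = window_grid[-1], mean_abs_diff = mu,
             ci_lo = mu - 1.96 * se, ci_hi = mu + 1.96 * se)
}
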