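test_that("pink noise satisfies its postconditions and spectral slope", {
  x <- generate_pink_noise(2 ^ 14, 500, 2, seed = 1)
  expect_lt(abs(mean(x)), 0.02)
  expect_equal(stats::sd(x), 1, tolerance = 0.02)
  # white noise: log-log slope ~ 0
  slope <- function(alpha, seeds) {
    mean(vapply(seeds, function(s) {
      x <- generate_pink_noise(2 ^ 14, 500, alpha, seed = s)
      p <- stats::spec.pgram(stats::ts(x, frequency = 500), spans = 31,
                             plot = FALSE, taper = 0)
      sel <- p$freq > 1 & p$freq < 200
      unname(stats::coef(stats::lm(log(p$spec[sel]) ~ log(p$freq[sel])))[2])
    }, numeric(1)))
  }
  expect_lt(abs(slope(0, 1:5)), 0.1)
  # alpha = 2: fitted slope within [-2.2, -1.8] averaged over seeds
  s2 <- slope(2, 1:10)
  expect_gt(s2, -2.2); expect_lt(s2, -1.8)
  expect_error(generate_pink_noise(1, 500), "invalid")
  expect_error(generate_pink_noise(100, 500, alpha = -1), "alpha")
})

test_that("cohort configs enforce their invariants", {
  expect_error(cohort_config("AS_like", complexity_gap = 1.2), "complexity_gap")
  expect_error(cohort_config("AS_like", mixing_strength = 1), "mixing")
  expect_error(cohort_config(
    "AS_like", dominant_band = list(wake = c(2, 4), nrem = c(1, 3))),
    "same dominant band")
  expect_error(generate_recording(cohort_config("AS_like", duration_s = 5),
                                  "p", "wake"), "10.9")
})

test_that("generation is seed-deterministic and ids are checked", {
  cf <- cohort_config("NT_like", n_participants = 2, duration_s = 20,
                      n_channels = 4, seed = 3)
  a <- generate_recording(cf, "p1", "wake", seed = 5)
  b <- generate_recording(cf, "p1", "wake", seed = 5)
  expect_identical(a$data, b$data)
  expect_identical(a$artifact_mask, b$artifact_mask)
  d <- generate_recording(cf, "p1", "wake", seed = 6)
  expect_false(identical(a$data, d$data))
  ds <- generate_dataset(cf, list(), seed = 1)
  expect_length(ds$records, 4)  # 2 participants x 2 states
  expect_equal(nrow(ds$manifest), 4)
  ds2 <- generate_dataset(cf, list(), seed = 1)
  expect_identical(ds$records[[1]]$data, ds2$records[[1]]$data)
  expect_error(generate_dataset(cf, list(cf), seed = 1), "duplicate")
})

test_that("the generation-time phase randomization preserves magnitudes exactly", {
  set.seed(6)
  x <- rnorm(4096)
  y <- eegstates:::partial_phase_randomize(x, 0.85)
  expect_lt(max(abs(Mod(stats::fft(x)) - Mod(stats::fft(y)))), 1e-8)
  expect_false(isTRUE(all.equal(x, y)))
})

test_that("AS-like regime: delta2 dominance with a spectrum/complexity dissociation", {
  # construction check averaged over seeds, as the design prescribes
  seeds <- 1:5
  rel_w <- rel_s <- matrix(NA, length(seeds), 6)
  pe_gap <- numeric(length(seeds))
  for (k in seq_along(seeds)) {
    cf <- cohort_config("AS_like", duration_s = 45, n_channels = 5,
                        seed = seeds[k], mask_fraction = 0)
    w <- average_reference(bandpass(
      generate_recording(cf, "p", "wake", seed = 100 + k)))
    s <- average_reference(bandpass(
      generate_recording(cf, "p", "nrem", seed = 200 + k)))
    rel_w[k, ] <- colMeans(band_power(morlet_psd(w), relative = TRUE))
    rel_s[k, ] <- colMeans(band_power(morlet_psd(s), relative = TRUE))
    w125 <- downsample(w, 125); s125 <- downsample(s, 125)
    pe <- function(r) mean(vapply(seq_len(nrow(r$data)), function(ch)
      permen_windowed(r$data[ch, ], 125, 32, mask = r$artifact_mask),
      numeric(1)))
    pe_gap[k] <- pe(w125) - pe(s125)
  }
  # delta2 is the maximal relative band in both states, every seed
  expect_true(all(apply(rel_w, 1, which.max) == 3))
  expect_true(all(apply(rel_s, 1, which.max) == 3))
  # matched spectra: seed-averaged log-power profiles differ by < 5% RMS
  lw <- log10(colMeans(rel_w)); ls <- log10(colMeans(rel_s))
  expect_lt(sqrt(mean((lw - ls) ^ 2)) / sqrt(mean(lw ^ 2)), 0.05)
  # ... while wake permutation entropy is strictly higher in every seed
  expect_true(all(pe_gap > 0))
})

test_that("spectral dissociation invariant: close band-power distributions, clear entropy gap", {
  # KS distance between wake and sleep relative band-power vectors stays
  # small for the dissociated regimes while the PermEn gap is positive
  for (regime in c("AS_like", "DUP_like")) {
    gaps <- numeric(3)
    for (k in 1:3) {
      cf <- cohort_config(regime, duration_s = 45, n_channels = 10,
                          seed = 9 + k, mask_fraction = 0)
      w <- average_reference(bandpass(generate_recording(cf, "p", "wake",
                                                         30 + k)))
      s <- average_reference(bandpass(generate_recording(cf, "p", "nrem",
                                                         60 + k)))
      bw <- colMeans(band_power(morlet_psd(w), relative = TRUE))
      bs <- colMeans(band_power(morlet_psd(s), relative = TRUE))
      expect_lt(max(abs(cumsum(bw) - cumsum(bs))), 0.1)
      w125 <- downsample(w, 125); s125 <- downsample(s, 125)
      gaps[k] <- mean(vapply(1:10, function(ch)
        permen_windowed(w125$data[ch, ], 125, 32), numeric(1))) -
        mean(vapply(1:10, function(ch)
          permen_windowed(s125$data[ch, ], 125, 32), numeric(1)))
    }
    expect_gt(mean(gaps), 0.005)
  }
})

test_that("uncoupled, unmixed channels show no spurious connectivity", {
  cf <- cohort_config("NT_like", duration_s = 150, n_channels = 6,
                      mixing_strength = 0, coupling_strength = 0,
                      mask_fraction = 0, seed = 4)
  rec <- generate_recording(cf, "p", "nrem", seed = 8)
  pn <- expand.grid(i = 1:6, j = 1:6)
  pn <- pn[pn$i < pn$j, ]
  pn$label_i <- "x"; pn$label_j <- "y"; pn$distance_mm <- 100
  pn$class <- "short"
  d <- dwpli(rec, pairs = pn)
  expect_lt(stats::quantile(abs(d$pair_band), 0.95, na.rm = TRUE), 0.1)
})

test_that("window-length validation behaves on the edge cases and for LZ", {
  # length-1 grid: empty table
  empty <- window_length_validation(3, "lz", window_grid = 10)
  expect_equal(nrow(empty), 0)
  # constant feature stub: all differences zero
  con <- window_length_validation(3, feature = function(x, fs, w) 42,
                                  window_grid = c(2, 4, 6, 8), fs = 200,
                                  duration_s = 10, seed = 2)
  expect_true(all(con$mean_abs_diff == 0))
  # LZ stability curve: the running mean |successive difference| is
  # non-increasing after its first quarter (scaled-down check)
  wl <- window_length_validation(12, "lz", window_grid = seq(2, 60, 2),
                                 fs = 500, alpha = 2, seed = 3)
  q <- floor(nrow(wl) / 4)
  tail_curve <- wl$mean_abs_diff[q:nrow(wl)]
  expect_true(all(diff(tail_curve) <= 1e-3))
  expect_error(window_length_validation(1, "lz"), "n_signals")
})
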