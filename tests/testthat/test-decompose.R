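test_that("phase randomization preserves the amplitude spectrum exactly", {
  set.seed(1)
  for (n in c(624, 625)) {  # even and odd lengths
    x <- rnorm(n)
    y <- phase_randomize(x, seed = 2)
    expect_lt(max(abs(Mod(stats::fft(x)) - Mod(stats::fft(y)))), 1e-9)
    expect_true(is.numeric(y))  # real output by construction
    # Wiener-Khinchin: autocorrelation preserved within sampling tolerance
    ax <- stats::acf(x, lag.max = 20, plot = FALSE)$acf
    ay <- stats::acf(y, lag.max = 20, plot = FALSE)$acf
    expect_lt(max(abs(ax - ay)), 0.05)
  }
})

test_that("phase swap keeps the amplitude donor's spectrum", {
  set.seed(3)
  a <- rnorm(600); b <- cumsum(rnorm(600))
  y <- phase_swap(a, b)
  expect_lt(max(abs(Mod(stats::fft(a)) - Mod(stats::fft(y)))), 1e-8)
  expect_error(phase_swap(a, b[1:10]), "equal length")
  # swapping a segment with itself returns the segment
  expect_equal(phase_swap(a, a), a, tolerance = 1e-10)
})

test_that("phase swap from a white-noise donor behaves like phase randomization", {
  # paired PermEn difference between swap-from-noise and full randomization
  # has a CI covering zero across seeds
  set.seed(4)
  diffs <- vapply(1:50, function(i) {
    a <- as.numeric(stats::filter(rnorm(625), 0.8, method = "recursive"))
    donor <- rnorm(625)
    s1 <- phase_swap(a, donor)
    s2 <- phase_randomize(a)
    pe <- function(x) perm_entropy(ordinal_symbolize(x, 3, 4))
    pe(s1) - pe(s2)
  }, numeric(1))
  ci <- mean(diffs) + c(-1.96, 1.96) * stats::sd(diffs) / sqrt(50)
  expect_lt(ci[1], 0); expect_gt(ci[2], 0)
})

test_that("the decomposition separates amplitude from phase structure", {
  set.seed(5)
  n <- 625  # 5 s at 125 Hz
  mk_segs <- function(gen) lapply(1:12, function(i) gen())
  # (a) amplitude-only contrast: both conditions phase-random, different
  #     spectral tilt
  wk <- mk_segs(function() generate_pink_noise(n, 125, 1.0))
  sl <- mk_segs(function() generate_pink_noise(n, 125, 2.2))
  d1 <- decompose_permen(wk, sl, taus_ms = 32, n_surrogates = 120, seed = 6)
  amp <- d1$value[d1$term == "amplitude"]
  tot <- d1$value[d1$term == "total"]
  nonamp <- d1$value[d1$term == "non_amplitude"]
  se <- d1$mc_se[d1$term == "non_amplitude"]
  expect_lt(abs(nonamp), 3 * se + 0.01)
  expect_gt(amp / tot, 0.9)
  # (b) phase-only contrast: identical amplitude spectra, different phase
  #     structure (each wake segment is a surrogate of a sleep segment)
  sl2 <- mk_segs(function() {
    t <- (0:(n - 1)) / 125
    # structured: frequency-modulated sweep plus a little noise
    ph <- 2 * pi * cumsum(4 * (1 + 0.4 * sin(2 * pi * 0.5 * t +
                                             stats::runif(1, 0, 6)))) / 125
    sin(ph) + 0.3 * rnorm(n)
  })
  wk2 <- lapply(sl2, phase_randomize)
  d2 <- decompose_permen(wk2, sl2, taus_ms = 32, n_surrogates = 120, seed = 7)
  amp2 <- d2$value[d2$term == "amplitude"]
  se2 <- d2$mc_se[d2$term == "amplitude"]
  tot2 <- d2$value[d2$term == "total"]
  expect_gt(tot2, 0.02)              # surrogates are more entropic
  expect_lt(abs(amp2), 3 * se2 + 0.01)
  # (c) identical conditions: all components collapse to zero
  d3 <- decompose_permen(sl[1:8], sl[1:8], taus_ms = 32, n_surrogates = 80,
                         seed = 8)
  expect_lt(max(abs(d3$value)), 0.02)
  # additivity is exact by construction
  for (d in list(d1, d2, d3)) {
    expect_equal(d$value[d$term == "total"],
                 sum(d$value[d$term %in% c("amplitude", "phase",
                                           "interaction")]),
                 tolerance = 1e-12)
  }
  expect_error(decompose_permen(wk[1:3], sl[1:4]), "balanced")
})

test_that("Monte-Carlo error shrinks like 1/sqrt(surrogates)", {
  set.seed(9)
  n <- 400
  wk <- lapply(1:8, function(i) generate_pink_noise(n, 125, 1.2))
  sl <- lapply(1:8, function(i) generate_pink_noise(n, 125, 2.0))
  d_small <- decompose_permen(wk, sl, taus_ms = 32, n_surrogates = 60,
                              seed = 10)
  d_big <- decompose_permen(wk, sl, taus_ms = 32, n_surrogates = 240,
                            seed = 10)
  ratio <- d_small$mc_se[d_small$term == "amplitude"] /
    d_big$mc_se[d_big$term == "amplitude"]
  expect_gt(ratio, 1.3); expect_lt(ratio, 3.1)  # ~2 expected
})

test_that("component statistics detect injected effects at the right rate", {
  sim_components <- function(gap, n_sub, seed) {
    set.seed(seed)
    do.call(rbind, lapply(seq_len(n_sub), function(p) {
      base <- rnorm(1, sd = 0.5)
      data.frame(participant_id = paste0("p", p), tau_ms = 32,
                 term = c("amplitude", "non_amplitude"),
                 value = base + c(rnorm(1), gap + rnorm(1)))
    }))
  }
  # power: true gap 0.6 SD of the paired difference scale, n = 30
  hits <- vapply(1:60, function(r) {
    cs <- component_stats(sim_components(0.6 * sqrt(2), 30, r))
    cs$significant[1]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  # type-I error near the nominal level under the null
  false_hits <- vapply(1:100, function(r) {
    cs <- component_stats(sim_components(0, 30, 1000 + r))
    cs$p[1] < 0.05
  }, logical(1))
  expect_lt(mean(false_hits), 0.12)
  # effect-size sign tracks the injected direction
  cs_pos <- component_stats(sim_components(1.5, 20, 5))
  expect_gt(cs_pos$cohens_d[1], 0)
  cs_neg <- component_stats(sim_components(-1.5, 20, 6))
  expect_lt(cs_neg$cohens_d[1], 0)
  expect_error(component_stats(sim_components(1, 2, 1)), "3 participants")
})

test_that("segment drawing respects masks and balance requirements", {
  rec <- noise_record(fs = 125, dur = 60)
  set.seed(11)
  segs <- draw_segments(rec, 1, n_segments = 10)
  expect_length(segs, 10)
  expect_true(all(lengths(segs) == 625))
  rec$artifact_mask[1:(125 * 55)] <- FALSE
  expect_error(draw_segments(rec, 1, n_segments = 10), "usable")
})
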