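test_that("ordinal symbolization follows the rank-pattern rules", {
  # strictly increasing signal: a single (ascending) symbol
  s <- ordinal_symbolize(1:50, m = 3, tau_samples = 2)
  expect_length(unique(s$symbols), 1)
  expect_length(s$opposite_map, 6)  # m = 3 alphabet
  # hand oracle: windows (4,1,3) and (1,3,2) have different rank patterns
  s2 <- ordinal_symbolize(c(4, 1, 3, 2), m = 3, tau_samples = 1)
  expect_length(s2$symbols, 2)
  expect_false(s2$symbols[1] == s2$symbols[2])
  # ties break by temporal order: (1,1,0) ranks as (earlier-lower): 1,2,0
  st <- ordinal_symbolize(c(1, 1, 0), m = 3, tau_samples = 1)
  se <- ordinal_symbolize(c(1, 1.0000001, 0), m = 3, tau_samples = 1)
  expect_identical(st$symbols, se$symbols)
  expect_error(ordinal_symbolize(c(1, 2), m = 3, tau_samples = 1), "short")
})

test_that("permutation entropy hits its analytic anchors", {
  expect_identical(perm_entropy(rep(0L, 10), m = 3), 0)
  expect_equal(perm_entropy(rep(0:5, 10), m = 3), 1)
  # counts {3,3,0,0,0,0} -> ln2/ln6
  expect_equal(perm_entropy(c(0L, 0L, 0L, 1L, 1L, 1L), m = 3),
               log(2) / log(6))
})

test_that("wSMI is zero under identity and sign flip, near zero when independent", {
  set.seed(11)
  x <- rnorm(5000)
  sx <- ordinal_symbolize(x, 3, 2)
  sflip <- ordinal_symbolize(-x, 3, 2)
  expect_identical(wsmi(sx, sx), 0)
  expect_identical(wsmi(sx, sflip), 0)
  sz <- ordinal_symbolize(rnorm(5000), 3, 2)
  expect_lt(abs(wsmi(sx, sz)), 0.02)
  expect_error(wsmi(sx, ordinal_symbolize(x, 3, 4)), "share")
})

test_that("mMSE matches a direct O(n^2) computation and known orderings", {
  set.seed(3)
  x <- rnorm(500)
  xs <- (x - mean(x)) / sd(x)
  direct <- fuzzy_sampen_direct(xs, 2, 0.15)
  fast <- eegstates:::fuzzy_sampen_counts_cpp(xs, 2L, 0.15)
  expect_equal(-log(fast[2] / fast[1]), -log(direct[2] / direct[1]),
               tolerance = 1e-10)
  # white noise: flat profile under the per-scale radius update
  set.seed(4)
  w <- rnorm(6000)
  pw <- mmse(w, mmse_config(scales = 1:10))$per_scale
  expect_true(all(is.finite(pw)))
  expect_lt(diff(range(pw)), 0.1)
  # AR(1)-correlated noise: lower at scale 1, rising with scale
  ar <- as.numeric(stats::filter(w, 0.9, method = "recursive"))
  pa <- mmse(ar, mmse_config(scales = 1:5, average_scales = 1:5))$per_scale
  expect_lt(pa[1], pw[1] - 0.2)
  expect_gt(pa[5], pa[1])
  # long-period square wave: near-zero scale-1 entropy
  sq <- rep(c(1, -1), each = 50, times = 60)
  expect_lt(mmse(sq, mmse_config(scales = 1, average_scales = 1))$per_scale[1],
            0.1)
  # constant signal: missing
  expect_true(is.na(mmse(rep(1, 6000))$value))
})

test_that("LZ76 calibrates on random and periodic sequences", {
  set.seed(7)
  x <- rnorm(1e5)
  v <- lz76(x, lzctw_config(segment_s = 500, fs = 200, min_samples = 2000))
  expect_gt(v, 0.95); expect_lt(v, 1.10)
  alt <- rep(c(1, -1), 5000)  # strict alternation around the median
  va <- lz76(alt, lzctw_config(segment_s = 50, fs = 200, min_samples = 2000))
  expect_lt(va, 0.05)
})

test_that("LZ76 parser agrees with the direct reference parse", {
  set.seed(8)
  for (i in 1:100) {
    bits <- sample(0:1, 64, replace = TRUE)
    expect_identical(eegstates:::lz76_count_cpp(bits), lz76_reference(bits))
  }
  # and with the Kaspar-Schuster routine on longer strings
  for (i in 1:20) {
    bits <- sample(0:1, 1000, replace = TRUE)
    expect_identical(eegstates:::lz76_count_cpp(bits),
                     eegstates:::lz76_count_ks_cpp(bits))
  }
})

test_that("CTW entropy rate calibrates on coin flips and periodic input", {
  set.seed(9)
  bits <- sample(0:1, 1e5, replace = TRUE)
  r <- eegstates:::ctw_rate_cpp(bits, 20L)
  expect_gt(r, 0.99); expect_lt(r, 1.01)
  per <- rep(c(0L, 1L), 5000)
  expect_lt(eegstates:::ctw_rate_cpp(per, 20L), 0.01)
  # depth-0 CTW equals the closed-form KT probability
  b10 <- c(1L, 0L, 1L, 1L, 0L, 1L, 0L, 0L, 1L, 1L)
  expect_equal(eegstates:::ctw_rate_cpp(b10, 0L), -kt_log2prob(b10) / 10,
               tolerance = 1e-12)
})

test_that("all five estimators are invariant to positive affine transforms", {
  set.seed(10)
  x <- as.numeric(stats::filter(rnorm(4000), c(0.6, 0.3), method = "recursive",
                                sides = 1))
  x[is.na(x)] <- 0
  y <- 3.7 * x + 11
  lc <- lzctw_config(segment_s = 20, fs = 200, min_samples = 2000)
  expect_equal(lz76(x, lc), lz76(y, lc), tolerance = 1e-12)
  expect_equal(ctw_entropy_rate(x, lc), ctw_entropy_rate(y, lc),
               tolerance = 1e-12)
  expect_equal(permen_windowed(x, 200, 20), permen_windowed(y, 200, 20),
               tolerance = 1e-12)
  sx <- ordinal_symbolize(x, 3, 2); sy <- ordinal_symbolize(y, 3, 2)
  expect_identical(sx$symbols, sy$symbols)
  set.seed(12)
  z <- rnorm(4000); sz <- ordinal_symbolize(z, 3, 2)
  expect_equal(wsmi(sx, sz), wsmi(sy, sz), tolerance = 1e-12)
  # mMSE standardizes per scale, so affine maps cancel
  expect_equal(mmse(x, mmse_config(scales = 1:3, average_scales = 1:3,
                                   segment_s = 20))$value,
               mmse(y, mmse_config(scales = 1:3, average_scales = 1:3,
                                   segment_s = 20))$value,
               tolerance = 1e-9)
})

test_that("windowing drops masked windows and reports missing when none valid", {
  set.seed(13)
  x <- rnorm(125 * 30)
  mask <- rep(TRUE, length(x))
  full <- permen_windowed(x, 125, 32, mask = mask)
  mask[1000:2000] <- FALSE
  partial <- permen_windowed(x, 125, 32, mask = mask)
  expect_true(is.finite(full) && is.finite(partial))
  expect_true(is.na(permen_windowed(x, 125, 32, mask = rep(FALSE, length(x)))))
  expect_true(is.na(lz76(x, lzctw_config(segment_s = 60, fs = 125),
                         mask = rep(FALSE, length(x)))))
})
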