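# small synthetic feature tables for the selection machinery
make_table <- function(n_participants = 10, cohorts = "A", effect = NULL,
                       n_feats = 3, seed = 1, feat_names = NULL) {
  set.seed(seed)
  if (is.null(feat_names)) feat_names <- paste0("PermEn", c(8, 16, 32))[1:n_feats]
  rows <- list()
  for (co in cohorts) {
    for (p in seq_len(n_participants)) {
      pid <- paste0(co, "_", p)
      base <- rnorm(n_feats, sd = 0.3)
      for (st in c("wake", "nrem")) {
        v <- base + rnorm(n_feats, sd = 0.2)
        if (!is.null(effect) && st == "nrem") v <- v + effect
        row <- data.frame(participant_id = pid, cohort = co, state = st,
                          usable_length_s = 60, t(v))
        names(row)[-(1:4)] <- feat_names
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("feature_table", "data.frame")
  out
}

test_that("pooled z-scoring standardizes every feature column", {
  tb <- make_table(cohorts = c("A", "B"))
  z <- zscore_pooled(tb)
  for (cn in c("PermEn8", "PermEn16", "PermEn32")) {
    expect_lt(abs(mean(z[[cn]])), 1e-9)
    expect_equal(stats::sd(z[[cn]]), 1, tolerance = 1e-9)
  }
  # two rows {0, 2} -> -0.707, +0.707 under the n-1 SD convention
  t2 <- make_table(n_participants = 1, n_feats = 1)
  t2$PermEn8 <- c(0, 2)
  z2 <- zscore_pooled(t2)
  expect_equal(z2$PermEn8, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # idempotent up to tolerance
  expect_equal(zscore_pooled(z)$PermEn8, z$PermEn8, tolerance = 1e-9)
  t2$PermEn8 <- c(1, 1)
  expect_error(zscore_pooled(t2), "zero-variance.*PermEn8")
})

test_that("LMM selection finds state effects and respects the strict threshold", {
  # a feature equal to the state indicator (plus tiny noise) z-scores to a
  # two-group split with |beta| ~ 2
  tb <- make_table(n_participants = 20, effect = c(1, 0, 0), seed = 2)
  tb$PermEn8 <- as.numeric(tb$state == "nrem") + rnorm(nrow(tb), sd = 0.01)
  z <- zscore_pooled(tb)
  sel <- lmm_select(z, "A")
  expect_equal(unname(abs(sel$betas["PermEn8"])), 2, tolerance = 0.05)
  expect_true("PermEn8" %in% unlist(sel$selected))
  # pure-noise features are rarely selected (n = 40 participants)
  tb0 <- make_table(n_participants = 40, n_feats = 3, seed = 3)
  z0 <- zscore_pooled(tb0)
  sel0 <- lmm_select(z0, "A")
  expect_lte(length(unlist(sel0$selected)), 1)
  # beta exactly at the threshold is NOT selected (strict inequality);
  # a constant within-state response forces the paired-difference fallback
  # with an exact beta of 0.5
  tbx <- make_table(n_participants = 6, n_feats = 1, seed = 4)
  tbx$PermEn8 <- ifelse(tbx$state == "nrem", 0.5, 0)
  selx <- lmm_select(tbx, "A")  # unscaled on purpose: beta = 0.5 exactly
  expect_equal(unname(selx$betas["PermEn8"]), 0.5, tolerance = 1e-10)
  expect_false("PermEn8" %in% unlist(selx$selected))
  expect_true(selx$fallback["PermEn8"])
})

test_that("PCA selection reproduces eigen arithmetic and orthonormal loadings", {
  # rank-1 differences: one component explains everything
  tb <- make_table(n_participants = 8, n_feats = 3, seed = 5)
  d <- rnorm(8)
  for (k in 1:3) {
    v <- tb[[paste0("PermEn", c(8, 16, 32)[k])]]
    v[tb$state == "wake"] <- v[tb$state == "wake"] * 0 +
      k * d[as.integer(factor(tb$participant_id))[tb$state == "wake"]]
    v[tb$state == "nrem"] <- 0
    tb[[paste0("PermEn", c(8, 16, 32)[k])]] <- v
  }
  sel <- suppressWarnings(pca_select(tb, "A"))
  pc <- sel$per_category$scEntropy
  expect_equal(pc$k, 1)
  expect_equal(pc$eigenvalues[1], 1, tolerance = 1e-9)
  L <- pc$loadings
  expect_equal(unname(t(L) %*% L), diag(ncol(L)), tolerance = 1e-9)
  # isotropic noise: k matches a reference eigendecomposition
  tb2 <- make_table(n_participants = 12, n_feats = 3, seed = 6)
  sel2 <- suppressWarnings(pca_select(tb2, "A"))
  pc2 <- sel2$per_category$scEntropy
  wk <- tb2[tb2$state == "wake", ]; sl <- tb2[tb2$state == "nrem", ]
  dmat <- as.matrix(wk[order(wk$participant_id), 5:7]) -
    as.matrix(sl[order(sl$participant_id), 5:7])
  ev <- eigen(stats::cov(dmat))$values
  k_ref <- which(cumsum(ev / sum(ev)) >= 0.9)[1]
  expect_equal(pc2$k, k_ref)
})

test_that("selection ignores validation-cohort rows entirely (leakage guard)", {
  tb <- make_table(n_participants = 10, cohorts = c("A", "B"),
                   effect = c(0.8, 0.5, 0), seed = 7)
  only_a <- tb[tb$cohort == "A", ]
  class(only_a) <- class(tb)
  sel_all <- lmm_select(tb, "A")
  sel_a <- lmm_select(only_a, "A")
  expect_identical(sel_all$betas, sel_a$betas)
  expect_identical(sel_all$selected, sel_a$selected)
  p_all <- suppressWarnings(pca_select(tb, "A"))
  p_a <- suppressWarnings(pca_select(only_a, "A"))
  expect_identical(p_all$per_category$scEntropy$loadings,
                   p_a$per_category$scEntropy$loadings)
})

test_that("selection is invariant to feature sign flips", {
  tb <- make_table(n_participants = 12, effect = c(1, -0.8, 0), seed = 8)
  z <- zscore_pooled(tb)
  z2 <- z; z2$PermEn8 <- -z2$PermEn8
  s1 <- lmm_select(z, "A"); s2 <- lmm_select(z2, "A")
  expect_equal(abs(s1$betas), abs(s2$betas), tolerance = 1e-6)
  expect_identical(s1$selected, s2$selected)
})

test_that("length robustness flags only length-dependent features", {
  tb <- make_table(n_participants = 25, n_feats = 3, seed = 9)
  tb$usable_length_s <- stats::runif(nrow(tb), 40, 300)
  tb$PermEn32 <- 0.01 * tb$usable_length_s + rnorm(nrow(tb), sd = 0.05)
  res <- length_robustness(tb)
  expect_equal(nrow(res), 3)  # one row per feature
  expect_true(res$significant[res$feature == "PermEn32"])
  expect_false(any(res$significant[res$feature != "PermEn32"]))
})
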