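make_xy <- function(n_per_class = 20, p = 3, sep = 2, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
             matrix(rnorm(n_per_class * p, mean = sep / sqrt(p)), ncol = p))
  y <- rep(c("nrem", "wake"), each = n_per_class)
  ids <- rep(paste0("p", 1:n_per_class), 2)
  list(x = x, y = y, ids = ids)
}

test_that("regularized logistic regression fits, separates, and is seeded", {
  d <- make_xy(sep = 6, seed = 1)
  m <- suppressWarnings(fit_rlr(d$x, d$y, d$ids, seed = 3))
  r <- evaluate(m, d$y, x = d$x)
  expect_equal(r$auc, 1)
  m2 <- suppressWarnings(fit_rlr(d$x, d$y, d$ids, seed = 3))
  expect_identical(m$lambda, m2$lambda)
  expect_error(fit_rlr(d$x, rep("wake", nrow(d$x)), d$ids), "one class")
  # permuted labels: grouped-CV AUC hovers near chance
  set.seed(4)
  dperm <- make_xy(sep = 4, seed = 5)
  # permute at the participant level so paired rows stay consistent
  flip <- sample(c(TRUE, FALSE), 20, replace = TRUE)
  yperm <- dperm$y
  for (pid in unique(dperm$ids)[flip]) {
    sel <- dperm$ids == pid
    yperm[sel] <- rev(yperm[sel])
  }
  mperm <- suppressWarnings(fit_rlr(dperm$x, yperm, dperm$ids, seed = 6))
  # evaluate on fresh data drawn from the same null
  dnew <- make_xy(sep = 0, seed = 7)
  rperm <- evaluate(mperm, dnew$y, x = dnew$x)
  expect_gt(rperm$auc, 0.35 - 1e-9)
  expect_lt(rperm$auc, 0.65 + 1e-9)
})

test_that("ROC evaluation covers the canonical cases", {
  y <- rep(c("wake", "nrem"), each = 50)
  perfect <- c(rnorm(50, 5), rnorm(50, -5))
  r <- evaluate(perfect, y)
  expect_equal(r$auc, 1)
  expect_equal(r$accuracy, 1)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)
  expect_equal(r$specificity, 1)
  anti <- -perfect
  expect_equal(evaluate(anti, y)$auc, 0)
  set.seed(8)
  rnd <- evaluate(rnorm(200), rep(c("wake", "nrem"), 100))
  expect_gt(rnd$auc, 0.4); expect_lt(rnd$auc, 0.6)
  expect_error(evaluate(rnorm(5), rep("wake", 5)), "both classes")
  # AUC equals the trapezoidal area of the returned curve
  sc <- rnorm(60); yy <- rep(c("wake", "nrem"), 30)
  rr <- evaluate(sc, yy)
  area <- sum(diff(rr$fpr) * (head(rr$tpr, -1) + tail(rr$tpr, -1)) / 2)
  expect_equal(rr$auc, area, tolerance = 1e-12)
})

test_that("participant bootstrap saturates at AUC 1 and is deterministic", {
  y <- rep(c("wake", "nrem"), 10)
  ids <- rep(paste0("p", 1:10), each = 2)
  scores <- ifelse(y == "wake", 1, -1)
  b <- bootstrap_auc(scores, y, ids, n_boot = 200, seed = 2)
  expect_equal(b$auc, 1)
  expect_equal(b$ci, c(1, 1))  # every resample yields 100% AUC
  b2 <- bootstrap_auc(scores + rnorm(20, sd = 2), y, ids, n_boot = 200,
                      seed = 9)
  b3 <- bootstrap_auc(scores + rnorm(20, sd = 2), y, ids, n_boot = 200,
                      seed = 9)
  expect_identical(b2$ci, b3$ci)
  expect_error(bootstrap_auc(scores[1:6], y[1:6], ids[1:6]), "5 participants")
})

test_that("AUC-to-z transform matches the printed arithmetic", {
  z0 <- auc_to_z(0.5, 10)
  expect_equal(z0$z, 0)
  expect_equal(z0$p_one_tailed, 0.5)
  z1 <- auc_to_z(1, 5)
  expect_equal(z1$U, 25)
  expect_equal(z1$z, 12.5 / sqrt(650 / 12), tolerance = 1e-6)
  expect_equal(z1$z, 1.6984, tolerance = 1e-4)
  expect_error(auc_to_z(0.9, 1), "N must")
  # the classical Mann-Whitney variance differs by design
  expect_gt(auc_to_z(1, 5, variance = "classical")$z, z1$z)
})

test_that("z-based p agrees with exact Mann-Whitney enumeration within 2x", {
  # N = 6 per class; classical-variance normal approximation vs full
  # enumeration of the 924 rank assignments, for AUC >= 0.8
  for (auc in c(0.8, 0.861, 0.917, 1)) {
    u <- auc * 36
    p_exact <- mw_exact_upper_p(u, 6)
    p_z <- auc_to_z(auc, 6, variance = "classical")$p_one_tailed
    expect_gt(p_z / p_exact, 0.5)
    expect_lt(p_z / p_exact, 2)
  }
})

test_that("AUC comparison z' follows the printed formula", {
  c0 <- compare_aucs(1.3, 20, 1.3, 20)
  expect_equal(c0$z_prime, 0)
  expect_equal(c0$p_two_tailed, 1)
  c1 <- compare_aucs(2, 39, 0, 39)
  expect_equal(c1$z_prime, 2 / sqrt(2 / 36), tolerance = 1e-9)
  expect_equal(c1$z_prime, 8.485, tolerance = 1e-3)
  c2 <- compare_aucs(0, 39, 2, 39)
  expect_equal(c2$z_prime, -c1$z_prime)
  expect_error(compare_aucs(1, 3, 1, 10), "exceed 3")
})

test_that("BH step-up matches the reference implementation exactly", {
  expect_equal(fdr_bh(0.03)$p_adjusted, 0.03)
  same <- fdr_bh(rep(0.02, 5))
  expect_true(all(same$p_adjusted == 0.02))
  set.seed(10)
  p <- runif(20)
  expect_equal(fdr_bh(p)$p_adjusted, stats::p.adjust(p, "BH"),
               tolerance = 1e-15)
  expect_identical(fdr_bh(p, 0.05)$rejected,
                   stats::p.adjust(p, "BH") < 0.05)
  expect_error(fdr_bh(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("univariate models classify indicators, not noise", {
  tb <- data.frame(participant_id = rep(paste0("p", 1:15), each = 2),
                   cohort = "A",
                   state = rep(c("wake", "nrem"), 15),
                   usable_length_s = 60)
  set.seed(11)
  tb$PermEn8 <- as.numeric(tb$state == "wake")  # perfect indicator
  tb$LZ <- rnorm(30)                             # pure noise
  class(tb) <- c("feature_table", "data.frame")
  uni <- univariate_models(tb, "A")
  expect_equal(uni$auc[uni$feature == "PermEn8"], 1)
  expect_lt(abs(uni$auc[uni$feature == "LZ"] - 0.5), 0.25)
  expect_true(any(uni$flag_ridge[uni$feature == "PermEn8"]) ||
              all(is.finite(uni$auc)))
  # set arithmetic for the AUC >= threshold intersection
  expect_identical(auc_intersection(uni, 0.9), "PermEn8")
})
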