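#!/usr/bin/env Rscript
# Feature selection on the training regime (mixed-model coefficients and
# PCA of the wake-sleep contrast), regularized logistic-regression training
# per feature category, and evaluation on the two validation regimes with
# participant-bootstrap AUC confidence intervals.

suppressPackageStartupMessages(library(eegstates))

ft <- read.csv("results/features.csv", check.names = FALSE)
class(ft) <- c("feature_table", "data.frame")
z <- zscore_pooled(ft)

sel_lmm <- lmm_select(z, "AS_like")
sel_pca <- suppressWarnings(pca_select(z, "AS_like"))
cat("LMM-selected features (|beta| > 0.5):\n")
print(lapply(sel_lmm$selected, unname))
jsonlite::write_json(
  list(betas = as.list(round(sel_lmm$betas, 3)),
       selected = sel_lmm$selected,
       pca_k = lapply(sel_pca$per_category, `[[`, "k")),
  "results/selection.json", auto_unbox = TRUE, pretty = TRUE)

perf <- list()
tr_rows <- z$cohort == "AS_like"
for (sel in list(sel_lmm, sel_pca)) {
  for (cat_name in unique(canonical_features()$category)) {
    X <- tryCatch(apply_selection(sel, z, cat_name), error = function(e) NULL)
    if (is.null(X) || ncol(X) == 0) next
    m <- suppressWarnings(fit_rlr(X[tr_rows, , drop = FALSE],
                                  z$state[tr_rows],
                                  z$participant_id[tr_rows], seed = 5))
    for (coh in unique(z$cohort)) {
      rows <- z$cohort == coh
      sc <- rlr_scores(m, X[rows, , drop = FALSE])
      r <- evaluate(sc, z$state[rows])
      bb <- bootstrap_auc(sc, z$state[rows], z$participant_id[rows],
                          n_boot = 1000, seed = 7)
      zz <- auc_to_z(r$auc, sum(z$state[rows] == "wake"))
      perf[[length(perf) + 1]] <- data.frame(
        selection = sel$method, category = cat_name, cohort = coh,
        auc = r$auc, ci_lo = bb$ci[1], ci_hi = bb$ci[2],
        accuracy = r$accuracy, z = zz$z, N = sum(z$state[rows] == "wake"))
    }
  }
}
performance <- do.call(rbind, perf)
write.csv(performance, "results/performance.csv", row.names = FALSE)
print(performance, digits = 3)
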