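#!/usr/bin/env Rscript
# Head-to-head AUC comparisons of matched entropy versus spectral categories
# (Mann-Whitney z machinery, BH-FDR), plus unregularized univariate
# classifiers and the cross-regime AUC >= 0.9 intersection.

suppressPackageStartupMessages(library(eegstates))

perf <- read.csv("results/performance.csv")
pairs <- list(c("fcEntropy", "fcSpectral"),
              c("scEntropy", "scSpectralA"),
              c("scEntropy", "scSpectralR"))
rows <- list()
for (selm in unique(perf$selection)) {
  for (pr in pairs) {
    for (coh in unique(perf$cohort)) {
      p1 <- perf[perf$selection == selm & perf$category == pr[1] &
                 perf$cohort == coh, ]
      p2 <- perf[perf$selection == selm & perf$category == pr[2] &
                 perf$cohort == coh, ]
      if (!nrow(p1) || !nrow(p2) || p1$N <= 3) next
      cc <- compare_aucs(p1$z, p1$N, p2$z, p2$N)
      rows[[length(rows) + 1]] <- data.frame(
        selection = selm, cohort = coh,
        comparison = paste(pr[1], "vs", pr[2]),
        auc_entropy = p1$auc, auc_spectral = p2$auc,
        z_prime = cc$z_prime, p = cc$p_two_tailed)
    }
  }
}
cmp <- do.call(rbind, rows)
fdr <- fdr_bh(cmp$p)
cmp$p_fdr <- fdr$p_adjusted
cmp$significant <- fdr$rejected
write.csv(cmp, "results/comparisons.csv", row.names = FALSE)
print(cmp, digits = 3)

ft <- read.csv("results/features.csv", check.names = FALSE)
class(ft) <- c("feature_table", "data.frame")
z <- zscore_pooled(ft)
uni <- univariate_models(z, "AS_like")
write.csv(uni, "results/univariate.csv", row.names = FALSE)
cat("\nfeatures with AUC >= 0.9 in every regime:\n")
print(auc_intersection(uni, 0.9))
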