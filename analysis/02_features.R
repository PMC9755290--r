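#!/usr/bin/env Rscript
# Extract the full 42-feature table (entropy + spectral, single-channel +
# connectivity) from the simulated recordings. mMSE runs on 10 s segments
# here (2 per recording) to keep the desk-scale runtime reasonable; all other
# estimators use their standard configurations.

suppressPackageStartupMessages(library(eegstates))

data_dir <- "results/data"
stopifnot(dir.exists(data_dir))
paths <- list.files(data_dir, pattern = "\\.bin$", full.names = TRUE)
records <- lapply(paths, read_fixture)

opts <- feature_opts(mmse = mmse_config(segment_s = 10, max_segments = 2))
t0 <- proc.time()
ft <- feature_table(records, opts, preprocess = TRUE, progress = TRUE)
cat(sprintf("features for %d recordings in %.1f min\n",
            nrow(ft), (proc.time() - t0)[3] / 60))

write.csv(ft, "results/features.csv", row.names = FALSE)
agg <- aggregate(ft[, c("PermEn32", "LZ", "CTW", "delta2R", "betaR")],
                 by = list(cohort = ft$cohort, state = ft$state), mean)
cat("cohort/state means of headline features:\n")
print(agg, digits = 3)
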