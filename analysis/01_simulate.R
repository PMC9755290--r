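#!/usr/bin/env Rscript
# Simulate the three-cohort testbed: a slow-wave-dissociated training regime
# (delta-dominant in wake AND sleep), a typical regime, and a beta-dissociated
# regime, 6 participants x 2 states each. Writes fixture files plus the run
# manifest under results/data/.

suppressPackageStartupMessages(library(eegstates))

seed <- 20260918L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

mk <- function(regime, s) cohort_config(regime, n_participants = 6,
                                        duration_s = 90, seed = s)
ds <- generate_dataset(mk("AS_like", 11), list(mk("NT_like", 12),
                                               mk("DUP_like", 13)),
                       seed = seed)
for (rec in ds$records) write_fixture(rec, out)
write.csv(ds$manifest, file.path(out, "manifest.csv"), row.names = FALSE)

cat(sprintf("wrote %d recordings (%d cohorts) to %s\n",
            length(ds$records), 3, out))
# quick sanity: the training regime should carry its slow phenotype in both
# states (relative delta2 power maximal)
rec <- ds$records[[1]]
rel <- colMeans(band_power(morlet_psd(average_reference(bandpass(rec))),
                           relative = TRUE), na.rm = TRUE)
cat("training-regime relative band power (wake):\n")
print(round(rel, 3))
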