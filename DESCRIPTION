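Package: eegstates
Title: EEG Biomarkers of Conscious State Across Abnormal Oscillatory Regimes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A testbed for evaluating spectral and entropy EEG biomarkers of
    conscious state (wakefulness versus NREM sleep) under cortical dynamics that
    dissociate oscillations from consciousness. Provides a seeded multichannel
    synthetic-EEG generator for three cohort regimes (slow-dominated, typical,
    and beta-dominated) in which wake and sleep can share amplitude spectra while
    differing in temporal complexity; preprocessing (FIR lowpass, Butterworth
    highpass, average reference, artifact-mask validity rules); Morlet-wavelet
    band power and debiased weighted phase lag index; five entropy estimators
    (permutation entropy, weighted symbolic mutual information, fuzzy multiscale
    sample entropy, Lempel-Ziv-76 complexity, context-tree-weighting entropy
    rate); mixed-model and PCA feature selection; regularized logistic-regression
    classifiers with grouped cross-validation, BCa bootstrap AUC confidence
    intervals and Mann-Whitney AUC comparison statistics with FDR control; and a
    phase-randomized surrogate decomposition of permutation-entropy changes into
    amplitude and non-amplitude components.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    lme4,
    glmnet,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
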