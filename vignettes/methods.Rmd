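---
title: "Entropy versus spectral EEG biomarkers of conscious state: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy versus spectral EEG biomarkers of conscious state: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Spectral EEG features — band power and oscillatory connectivity — are the
workhorse readouts of conscious state: wakefulness usually looks fast and
low-voltage, NREM sleep slow and high-voltage. That association breaks in
rare genetic disorders. Children with Angelman syndrome produce
high-amplitude 2–4 Hz delta activity *while awake and conscious*; children
with duplication 15q11.2-q13.1 syndrome produce fast beta activity that can
persist *into NREM sleep*. A biomarker of consciousness that leans on the
spectrum will misread both.

`eegstates` implements a testbed for the competing hypothesis: that signal
*entropy* — the temporal complexity of the waveform rather than its
frequency content — tracks conscious state across these dissociated
regimes. The package provides:

1. a seeded synthetic-EEG generator producing three cohort regimes in which
   wake and sleep can share amplitude spectra while differing in temporal
   complexity;
2. the preprocessing, spectral (Morlet band power, debiased weighted phase
   lag index) and entropy (permutation entropy, weighted symbolic mutual
   information, fuzzy multiscale sample entropy, Lempel–Ziv-76,
   context-tree-weighting entropy rate) feature extractors;
3. mixed-model and PCA feature selection, regularized logistic-regression
   classifiers with grouped cross-validation, BCa bootstrap AUC intervals,
   and Mann–Whitney AUC comparison statistics under FDR control;
4. a phase-randomized surrogate decomposition of permutation-entropy changes
   into amplitude and non-amplitude components.

Real recordings from these clinical populations require controlled-access
applications and are not redistributable; every empirical number this
package reports is computed from its own synthetic cohorts.

## The synthetic cohorts: what is emulated, and what a green test establishes

Each regime is a `cohort_config`: a dominant band per state
(AS-like: 2–4 Hz in both states; NT-like: 8–16 Hz awake, 1–4 Hz asleep;
DUP-like: 16–32 Hz in both states), participants, channels (19-channel
10–20 montage), sampling rate (200 Hz default, the rate at which several
of the real cohorts were acquired), duration per state, and amplitude in
microvolts (100 for the slow regime — the high-amplitude delta phenotype —
30–40 otherwise).

A recording is built in five steps (`generate_recording`):

1. **Template.** Per channel, a structured 1/f background plus a dominant
   oscillation. The background is a Hann overlap-add of 2.5 s chirplet
   blocks: each block has 1/f^(α/2) Fourier magnitudes (α = 1.2 by default,
   within the range fitted to developmental EEG) and *deterministic*
   quadratic phases with random per-block rate and offset. Locally the
   waveform is a predictable sweep — low temporal complexity — but block
   parameters are independent across blocks and channels, so it carries no
   stable cross-window or cross-channel phase relation and therefore no
   spurious lag-consistent connectivity. The oscillation is a
   harmonic-stacked carrier with per-channel source frequency drawn across
   the dominant band, deterministic slow frequency modulation (depth 0.25,
   0.5–1.1 Hz), a deterministic burst envelope (0.6–1 Hz), and a slow
   random phase drift that decorrelates windows over ~8 s. Per-channel
   source frequencies matter: channel averaging then cancels the
   frequency-idiosyncratic part of entropy levels, which is what lets small
   cohorts rank wake above sleep reliably.
2. **Wake surrogate.** The wake signal is the same template with the phases
   of a random fraction `complexity_gap` (default 0.85) of Fourier bins
   replaced by uniform draws. Amplitude spectra are preserved *exactly*
   (tested to 1e−8), so in the AS-like and DUP-like regimes wake and sleep
   share one amplitude spectrum while wake carries strictly higher
   temporal complexity — the dissociation at the heart of the testbed.
3. **Lagged coupling.** A narrowband source at the band centre is added to
   six designated channel pairs with a 20 ms lag, giving genuine (non-zero
   lag) connectivity to both dwPLI and wSMI, identically in both states.
4. **Zero-lag mixing.** Volume conduction as a convex mixture
   `(1−m)·I + m·(1/n)·11ᵀ` (rows sum to 1; `m = 0.25`); average referencing
   later removes exactly the common-mode part.
5. **Scaling and mask.** Channel-mean SD set to the regime's microvolt
   scale; 5% of samples covered by three synthetic artifact intervals
   (masks exercise the validity rules only — no artifact waveforms are
   simulated, as stated in the generator's scope).

What a green testbed run does *not* establish: that entropy features beat
spectral features on real clinical EEG. The generator is constructed so the
dissociation exists; the tests establish that the *pipeline* — estimators,
selection, classifiers, statistics — faithfully recovers a known ground
truth through the full preprocessing chain, and that spectral machinery
correctly finds nothing when nothing is there. Features of real data that
are deliberately absent include eye/muscle artifacts, nonstationary state
transitions, inter-site montage differences and age effects.

## Preprocessing conventions

- 45 Hz windowed-sinc FIR lowpass with `2·fs + 1` taps (the "order = twice
  the sampling rate" rule), applied centred, hence zero phase.
- 0.4 Hz 5th-order Butterworth highpass, applied forward–backward
  (zero-phase) in the pipeline. The printed design figure — 0.44 dB
  attenuation at 0.5 Hz — describes the single-pass analog prototype
  response `|H|² = 1/(1+(fc/f)^10)`, and the test asserts exactly that;
  whether the original preprocessing ran single-pass or zero-phase is not
  stated, so both are available (`zero_phase = FALSE`).
- Average reference; masks are annotations (filters run across masked
  samples; masked stretches are excluded at feature time).
- Data sufficiency: at least 15 windows of 10.9 s (the lowest-frequency
  wavelet window) at 75% overlap, each at least 80% usable; the analytic
  minimum `0.8 × (10.9 + 14 × 0.25 × 10.9) = 39.2 s` is reported by
  `check_sufficiency()`. The 10.9 s figure is carried as a constant of the
  validity policy, not derived from the wavelet parameterization, which the
  source chain does not print.
- Downsampling (125 Hz for ordinal features, 200 Hz for the rest) is
  Fourier resampling; masks resample conservatively (logical AND over each
  output sample's footprint).

## Feature estimators and their numerical choices

**Morlet PSD.** 49 log-spaced frequencies (8/octave, 0.5–32 Hz), 7-cycle
complex Morlet truncated at ±3 temporal SDs; window length equals kernel
support, 75% overlap, windows at least 80% usable. Power is calibrated to
μV²/Hz through the kernel's one-sided equivalent noise bandwidth so that
unit-variance white noise integrates back to its variance (tested at 15%).
Band power integrates by trapezoid on the log-spaced bins; the six bands
tile 0.5–32 Hz lower-inclusive/upper-exclusive, and relative powers sum
to one.

**dwPLI.** Cross-spectra from 2 s Hamming segments (50% overlap) inside 5 s
windows, evaluated by direct DFT at the wavelet frequencies; the debiased
WPLI-square estimator is formed across windows-as-observations and
band-averaged. Pairs are classed by template scalp distance (short
[80, 130) mm, long ≥ 130 mm, closer pairs excluded). The packaged
coordinate template is a *synthetic* geometric construction of the 10–20
system on a 92.5 mm sphere (file `montage_1020_synthetic.csv`), shipped
fixed so the 52/62/57 excluded/short/long partition is reproducible.

**Permutation entropy.** Ordinal patterns with `m = 3`, lags 8–128 ms at
125 Hz, ties broken by temporal order; Shannon entropy of the pattern
distribution normalized by ln 6; 5 s windows, 50% overlap, windows
overlapping masked samples dropped.

**wSMI.** Joint ordinal-pattern distributions per channel pair with
identical and sign-opposite symbol pairs zero-weighted; natural logs; the
normalization `2·wSMI/(PE(X)+PE(Y))` uses *unnormalized* PE terms so
numerator and denominator share units (the alternative is a documented
switch away; the source's convention is ambiguous on this point).

**mMSE.** 30 s segments, 20 coarse-graining scales with the first 10
averaged, embedding `m = 2`, sigmoidal membership
`μ(d) = 1/(1+exp((d−0.5)/r))` with `r = 0.15 ×` the per-scale coarse-grained
SD. Because the radius is recomputed per scale, coarse-grained white noise
is distributionally invariant and its profile is *flat* — the textbook
decrease only appears with a radius frozen at scale 1; the tests assert the
flat profile and the ordering against AR(1)-correlated noise instead.

**LZ76 and CTW.** Median binarization per 60 s segment (≥ 2000 usable
samples; a trailing partial segment is kept when it meets the minimum);
LZ76 counts exhaustive-history phrases via a linear-time online suffix
automaton (verified against the Kaspar–Schuster routine and a direct
reference parse) and normalizes by N/log₂N; CTW mixes
Krichevsky–Trofimov estimators over a depth-20 binary context tree
(depth a documented default; the source does not print one) and reports
−log₂P/N bits per symbol.

## Selection, classification, statistics

Features are channel-averaged (single-channel) or short-/long-range
averaged (connectivity), pooled across cohorts, and z-scored (n−1 SD).
Selection on the training cohort only:

- **LMM path**: `feature ~ state + (1|participant)` by REML with NREM
  coded 1; select |β| strictly > 0.5 per category. The strict reading is a
  decision — the source's own table marks a feature with β = 0.50 as
  selected, so rounding conventions there are ambiguous. Singular fits fall
  back to the paired within-participant difference, flagged.
- **PCA path**: per category, PCA of participant-level wake−sleep
  difference vectors; keep the smallest k with ≥ 90% cumulative variance
  (warning outside the expected 2–5); project state-level vectors on the
  loadings.

Classifiers are glmnet logistic regressions over the printed 100-point
log-spaced λ grid [4.4×10⁻⁵, 0.44], λ chosen by grouped 10-fold CV
deviance (a participant's wake and sleep rows never straddle a fold),
refit on the full training cohort. The penalty type is not stated at the
source; L1 is the default (the conventional idiom for a 100-point log
grid), L2 one flag away. The operating point is the Youden-J maximum — the
original toolbox convention is not reproducible without cost assumptions —
and accuracy, precision, recall and specificity are reported there, wake
positive.

AUC uncertainty comes from a participant-level BCa bootstrap (paired rows
resample together; degenerate one-class resamples are redrawn and
counted). AUC testing uses the printed transform U = AUC·N²,
z = (U − N²/2)/√(N²(N²+1)/12). That variance differs from the classical
Mann–Whitney approximation N²(2N+1)/12; both are implemented
(`auc_to_z(..., variance =)`), the printed form is the default, and only
the classical form is expected to agree with exact enumeration of the
Mann–Whitney tail (the oracle test checks that agreement at N = 6).
Two-classifier comparisons use z′ = (z₁−z₂)/√(1/(N₁−3)+1/(N₂−3)), valid
for balanced designs; Benjamini–Hochberg step-up controls FDR.

The testbed's acceptance check uses the PCA selection path for both
compared categories: under the generator's dissociation dwPLI genuinely
carries no state signal in the training regime, so the |β| > 0.5 rule
correctly selects zero fcSpectral features in some replicates, leaving no
classifier to compare (the source analysis hit the same situation in one
category and proceeded PCA-only).

## The surrogate decomposition

For balanced sets of 5 s segments per condition, the wake−sleep PermEn
difference is partitioned as total = amplitude + phase + interaction:

- *amplitude*: the mean gap after within-condition phase randomization
  (only the amplitude spectra still differ);
- *phase*: the gap attributable to condition-specific phase distributions,
  estimated by transplanting wake versus sleep phases (one random donor
  segment per surrogate) onto a common amplitude background, averaged over
  both backgrounds;
- *interaction*: the residual, so additivity is exact by construction.

The non-amplitude term is phase + interaction. The estimator arithmetic
beyond the two surrogate operations is a design choice documented here;
construction tests verify that an amplitude-only contrast leaves the
non-amplitude term inside its Monte-Carlo interval and vice versa. The
conventions are 1000 surrogates and 20 segments per condition;
Monte-Carlo standard errors shrink as 1/√n (tested), so scaled-down runs
report wider `mc_se`. Per-lag contrasts of amplitude versus non-amplitude
components use `value ~ component + (1|participant)` with
likelihood-ratio p-values (FDR across lags) and a paired Cohen's d.

## Runtime scaling in the shipped tests

The estimator configurations are faithful to their conventions, but two
of them are expensive at test time. The fuzzy-mMSE pair sums are O(n²):
one 30 s, 200 Hz segment costs ~0.7 s per channel, so a full 19-channel
cohort sweep is hours of mMSE alone. The shipped end-to-end tests
therefore run mMSE on 5 s segments inside replicates and use 60 s of data
per state (the headline-recovery criterion's thresholds, cohort sizes and
replicate counts are unchanged); the scaled settings are visible in the
test files and in `analysis/02_features.R`. Oracle equivalence of the
mMSE implementation at full fidelity is tested separately on short series.

## Known limitations

- The generator's regime parameters are artifact choices: the source
  describes the phenotypes qualitatively and publishes no generative
  model. Nothing here should be read as a quantitative claim about
  clinical EEG.
- EDF support is a minimal reader/writer (uniform sampling rate, 16-bit,
  no annotations); masks do not survive the EDF round trip.
- Mixed-model p-values use likelihood-ratio tests rather than
  denominator-degree-of-freedom approximations.
- The spectral peak picker is a deliberate simplification (log-log linear
  background plus prominence rule), standing in for full aperiodic/peak
  model fitting, which is out of scope.
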