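---
title: "Estimating EEG maturational age in preterm infants: models and design choices"
author: "neoEMA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating EEG maturational age in preterm infants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoEMA)
```

## The problem

The EEG of a preterm infant changes predictably with post-menstrual age
(PMA): the discontinuous tracé of the extremely preterm — brief
high-amplitude bursts (spontaneous activity transients, SATs) separated by
long low-amplitude inter-SAT intervals — gives way to continuous activity,
with rising amplitude, shortening inter-SAT intervals and growing
interhemispheric synchrony.  neoEMA turns these regularities into an *EEG
maturational age* (EMA): a regression estimate of the infant's age, in
days, computed from an hour of cot-side EEG.  Compared against the
clinically determined PMA, the EMA serves as an objective summary of
functional cortical maturation for serial bedside monitoring.

## The pipeline

1. **Preprocessing.** Referential (Cz) signals from 8 scalp electrodes are
   band-pass filtered 0.5–32 Hz, resampled to 64 Hz, re-montaged to the
   standard 8-derivation bipolar layout (Fp1-C3, C3-O1, Fp1-T3, T3-O1 and
   right homologues), and cut into 1-h epochs with 75 % overlap.
2. **SAT detection.** A rectified cross-form nonlinear energy operator
   (NLEO), `psi[n] = |x[n]x[n-3] - x[n-1]x[n-2]|`, smoothed over 1.5 s,
   is thresholded per channel; the epoch-level consensus annotation keeps
   intervals supported by at least half the channels.  The SAT% trace
   (fraction of a 5-min window covered by SATs, advancing by 1 min)
   delimits the low-SAT% segment, a proxy for quiet sleep.
3. **Artefact rules.** A SAT containing any sample above 500 µV is
   artefactual; an epoch with more than 20 % artefactual time is rejected.
   A bipolar channel whose median envelope falls below half the median
   over time and channels is excluded, as are channels derived from a
   referential electrode that is both relatively depressed and absolutely
   small (95th-percentile envelope under 25 µV); any exclusion rejects
   the epoch.
4. **Features.** 23 summaries — envelope percentiles (50/95), range-EEG
   percentiles (5/50/95), absolute and relative band powers (delta 0–3,
   theta 3–8, alpha 8–15, beta 15–30 Hz, plus total), SAT timing
   statistics (rate, duration and inter-SAT-interval percentiles, ISI
   RMS) and an activation synchrony index — each computed on the full
   epoch and on the low-SAT% segment: 46 features.
5. **Regression.** Radial-kernel support vector regression maps
   standardised features to age in days, inside a leave-one-infant-out
   cross-validation with backward feature elimination (secondary 10-fold
   CV) and hyperparameter grid search (internal 3-fold CV).
6. **Evaluation.** A linear mixed model (fixed slope, random intercept
   per infant) yields the repeated-measures correlation; error metrics,
   serial-growth analysis and reduced-montage comparisons (paired
   Wilcoxon signed-rank on squared errors) complete the report.

## Design decisions in detail

### Filters and resampling

The band-pass is split into zero-phase Butterworth stages (order 4
high-pass at 0.5 Hz, order 8 low-pass at 32 Hz, each run forward and
backward).  The contract is spectral, not structural: the squared response
keeps 1–25 Hz tones within 5 % and attenuates 0.1 Hz and 45 Hz by more
than 20 dB.  An order-4 low-pass fails the 25 Hz clause under
forward-backward filtering (its squared gain at 25/32 of the cut-off is
0.88), which is why the low-pass is order 8.  Zero-phase filtering is
essential: SAT onsets feed interval statistics, and any group delay would
bias them.  Resampling to 64 Hz is plain decimation when the native rate
is an integer multiple (the 32 Hz low-pass is the anti-alias filter) and
polyphase resampling otherwise.

### SAT detector parameterisation

The detector thresholds the 1.5 s-smoothed NLEO at θ = 1.5 µV², merges
below-threshold gaps shorter than 1 s and drops intervals shorter than
1 s.  Because the long centred smoother blurs boundaries by half its
length, interval edges are refined on a 0.25 s-smoothed NLEO with a
relative floor (10 % of the interval's peak) that keeps the refinement
from latching onto broadband noise; onsets then land within ~0.2 s of
truth on synthetic bursts.

θ is a calibration constant coupled to the amplitude regime of the
signal.  The calibration contract — at default settings, at least 95 % of
synthetic bursts of 25 µV or more are detected and at most 5 % of
detections fall in pure inter-burst background — is part of the test
suite.  NLEO responds to amplitude² × frequency², so the tolerable
inter-burst floor depends on its spectrum; for the strongly delta-dominant
floor the generator produces, the measured operating point is a bipolar
floor below ~1.6 µV RMS, and both contract clauses hold with margin
across the cohort's age range (measured 100 % / 0 % on clean epochs).

### Low-SAT% segmentation

"Low" is the 25th percentile of the SAT% values.  Below-threshold runs
shorter than 5 minutes are eliminated, and the threshold is recomputed
from the remaining windows before the final mask is emitted (a two-pass
reading; a single-pass variant is available via
`emaParams(lowsat_method = "single_pass")`).  Run duration is measured as
the time the trace stays below threshold (number of windows × step):
measuring the windows' time *span* instead would make the 5-min rule
vacuous, since a single 5-min window already spans 5 minutes.  A constant
trace cannot discriminate and yields a full-epoch mask with a warning; if
no run survives elimination, the longest below-threshold run is used,
also with a warning.

### Feature aggregation

Every amplitude/spectral feature is estimated per channel and summarised
by the median across non-excluded channels.  Cross-channel medians are
not additive, so the four relative band powers are renormalised to sum to
exactly 1 after aggregation.  Spectral estimates use Welch averaging
(2 s Hamming segments, 50 % overlap); within the low-SAT% segment only
segments fully inside the mask contribute, which avoids stitching
artefacts at mask boundaries.  Inter-SAT intervals are computed only
between SATs in the same contiguous mask block — a gap spanning a hole in
the mask is not an ISI.  SAT-timing features use the consensus annotation
(SATs are spatially widespread events; one SAT% per epoch), while the
per-channel annotations feed the 500 µV rule and the synchrony index.
The envelope roster is limited to the 50th and 95th percentiles; the
activation synchrony index is a coincidence ratio
`P(both active) / (P(left) P(right))` on 1-s binarised SAT activity of
homologous derivation pairs, with the median over valid pairs.

### Regression protocol

Targets stay in days; features are z-scored with training-fold constants.
The hyperparameter grid is log-spaced (C ∈ 2⁻²…2⁶, ε ∈ {0.5, 1, 2, 4, 8}
days, γ ∈ 2⁻⁶…2²/p); among settings whose CV MSE lies within one
standard error of the minimum, the least complex wins (largest ε, then
smallest C, then smallest γ) — with hundreds of candidates and a noisy
3-fold estimate, the raw minimiser systematically overfits the CV folds,
which a null (pure-noise) control exposes as held-out MSE inflated well
beyond the target variance.  Backward elimination walks the complete path from
46 features to 1, dropping at each step the feature whose removal
minimises the 10-fold CV MSE (ties go to the lower roster index), and
returns the subset at the path minimum (the smallest subset among tied
minima).  Hyperparameters are optimised once per training fold at the
full feature set and held fixed along the elimination path, with γ
rescaled in proportion to 1/p as features are removed so the kernel
bandwidth per feature stays constant — mirroring the grid's own γ
convention.  Re-optimising the full grid inside every candidate
evaluation (~400× the compute) changes no ranking in practice at this
cohort size; the final model is refit with a fresh grid search on the
selected subset.  Missing feature values (e.g. fewer than two SATs in a
short low-SAT% segment) are imputed with training-fold medians — never
with test-fold statistics — and per-recording EMA averages the epoch
feature vectors within a recording before predicting once (predicting
per epoch and averaging the EMAs is available via
`runLOIO(perRecording = FALSE)`).  Cross-validation folds are grouped by
infant at every level, so no infant ever straddles a split.

### Evaluation definitions

The repeated-measures "adjusted" correlation is the Pearson correlation
between PMA and the random-intercept-corrected EMA (EMA − b̂ᵢ) from the
mixed model EMAᵢⱼ = β₀ + β₁ PMAᵢⱼ + bᵢ + εᵢⱼ (REML); a singular fit
falls back to ordinary regression with a warning.  The percentage error
is the mean absolute error as a percentage of mean PMA.  "Within k weeks"
means |EMA − PMA| ≤ 7k days, so an error of exactly 14 days counts as
within two weeks and 15 days does not.  Serial growth flags an infant as
increasing when the last EMA exceeds the first; non-increasing
consecutive pairs are attributed to outlier recordings (|EMA − PMA| > 14
days).  The paired montage test is the two-sided Wilcoxon signed-rank on
per-recording squared errors with zero differences dropped; all paired
differences being zero reports p = 1.  Tie thresholds in the artefact
rules are strict inequalities ("less than 50 %", "more than 20 %"), so
exact ties never exclude.

## The synthetic cohort

No clinical recordings ship with the package; the generator provides the
study conditions with known ground truth.  Per hemisphere it alternates
inter-SAT background (shaped Gaussian noise, strongly delta-dominant,
0.85→1.15 µV RMS per referential electrode across 24→38 weeks) with SAT
bursts (band-weighted noise under a raised-cosine envelope, 15→35 µV
RMS, beta weight rising with age).  The mean inter-SAT interval falls
30→6 s, mean SAT duration grows 3→5 s, and homologous channels share
burst onsets with probability 0.5→0.9.  A quiet-sleep block covering
30 % of the recording doubles the local ISI (normalised so the
recording-wide mean stays nominal), giving the low-SAT% segmentation
something real to find.  Serial designs draw each infant's first
recording at 24–32 weeks with 18–30 days between recordings, and
per-infant multiplicative jitter (±8 % ISI, ±10 % amplitude) adds
between-subject variability.  Artefact injection (>500 µV excursions
inside scheduled SATs; electrodes scaled to 5 %) is off by default and
exercised explicitly in tests.

What the generator does *not* emulate: real burst morphology (delta
brushes, temporal theta), sleep-cycle architecture beyond one two-level
state, electrode-specific spectra, line noise, or biological decoupling
between amplitude and timing trends.  Passing tests therefore demonstrate
that the pipeline recovers the *kind* of structure it models, at
realistic signal scales — not clinical performance.  On the default
synthetic cohort the full pipeline reaches a repeated-measures
correlation above 0.99 with every infant's EMA increasing between first
and last recording; clinical EEG carries biological variability the
generator does not model, so real-data accuracy will be lower, and the
acceptance checks are accordingly property-based (correlation ≥ 0.8,
100 % first-to-last growth) rather than numeric reproductions.

## Problem sizes and numerical choices

Simulation studies in the test suite and the acceptance script use
10-minute recordings with proportionally scaled SAT% windows (50 s
window, 10 s step, 50 s minimum run) — the epoch:window ratios of the
full-length analysis — and a 30-infant cohort; these sizes keep a full
run to minutes while leaving every stage statistically meaningful.  The
selection hot loop calls libsvm's training routine directly (verified
identical to `e1071::svm` to 1e-14 in the test suite) because the
wrapper's R-side overhead would otherwise triple the cost of the ~10⁴
SVR fits per training fold.  EMA predictions are clamped to [140, 320]
days with a warning.  Degenerate inputs are first-class: constant
targets raise a degenerate-fit error, all-noise feature sets select with
a warning, zero signals yield zero band powers with missing relative
powers, and fewer than two SATs yield missing ISI features.

## Worked example

```{r example, eval = FALSE}
library(neoEMA)
cohort <- generateCohort(simConfig(n_infants = 8, rec_dur_s = 600), seed = 7)
features <- buildFeatureSet(cohort$recordings, emaParams(epoch_s = 600))
cv <- runLOIO(features, featureSelection = FALSE, seed = 7)
report <- evaluateEMA(cv$ema)
report$adjusted_r
report$mse_days2
report$growth$pct_increasing_first_last
```

## Known limitations

* The activation synchrony index is a coincidence-ratio surrogate, not a
  reimplementation of the original index from the neonatal EEG
  literature.
* The exact reading of the "lower quartile range" low-SAT% threshold is
  ambiguous; both the two-pass default and a single-pass variant are
  provided.
* EDF support covers the common 16-bit uniform-rate subset used by
  clinical exports; EDF+ annotations are skipped, not parsed.
* The hyperparameter grid is fixed rather than adaptive; for targets far
  outside the neonatal age range the ε grid (in days) would need
  rescaling.
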