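# neoEMA — EEG maturational age for preterm infants

Preterm infants spend their last trimester in the NICU, where functional
brain maturation can be followed at the cot side with EEG.  The EEG of an
extremely preterm infant is discontinuous — high-amplitude bursts
(spontaneous activity transients, SATs) separated by long quiet inter-SAT
intervals — and matures in a predictable way: amplitudes grow, inter-SAT
intervals shrink, activity becomes continuous and interhemispherically
synchronous.  **neoEMA** condenses these regularities into a single
number, the *EEG maturational age* (EMA): a support-vector-regression
estimate of the infant's post-menstrual age (PMA, in days) computed from
multichannel EEG.  Tracking EMA against PMA over serial recordings gives
neonatologists and researchers an objective measure of functional brain
maturation.

## The method

For each 1-h epoch (75 % overlap) of band-passed (0.5–32 Hz), 64 Hz,
bipolar-montage EEG:

* SATs are detected per channel with a smoothed nonlinear energy operator
  `ψ[n] = |x[n]x[n−3] − x[n−1]x[n−2]|` and combined into a consensus
  annotation; the SAT% trace (coverage of a 5-min sliding window)
  delimits a low-SAT% segment, a proxy for quiet sleep.
* Two amplitude rules screen artefacts: SATs exceeding 500 µV mark
  contaminated time (epochs > 20 % contaminated are rejected), and
  channels with depressed envelopes (below 50 % of the cross-channel
  median, or derived from a flat referential electrode) reject the epoch.
* 23 features — envelope and range-EEG percentiles, band powers (δ 0–3,
  θ 3–8, α 8–15, β 15–30 Hz), SAT timing statistics and an activation
  synchrony index — are computed on the full epoch and on the low-SAT%
  segment: 46 features.
* A radial-kernel SVR maps the features to age in days inside a
  leave-one-infant-out cross-validation with backward feature elimination
  (10-fold CV) and grid-searched hyperparameters (3-fold CV).
* Evaluation uses a linear mixed model (fixed slope, random intercept per
  infant) for the repeated-measures correlation, plus error metrics,
  serial-growth analysis and reduced-montage comparisons (paired Wilcoxon
  signed-rank).

Clinical EEG is not distributable, so the package ships a synthetic
cohort generator (`generateCohort()`) with age-dependent burst statistics
and known ground truth; every stage is tested against it.  See the
methods vignette (`vignettes/ema-methods.Rmd`) for assumptions, parameter
choices and limitations.

## Worked example

```r
library(neoEMA)

# synthetic cohort: 30 infants, 2-4 serial recordings, PMA 24-38 wk,
# 10-minute recordings with proportionally scaled analysis windows
cohort   <- generateCohort(simConfig(rec_dur_s = 600), seed = 1)
features <- buildFeatureSet(cohort$recordings, emaParams(epoch_s = 600))
cv       <- runLOIO(features, featureSelection = TRUE, seed = 1)
report   <- evaluateEMA(cv$ema)

report$adjusted_r                          # 0.996
report$mse_days2                           # 6.04
report$growth$pct_increasing_first_last    # 100
median(lengths(cv$selection))              # 2
```

`adjusted_r` is the repeated-measures correlation between EMA and true
age (random infant intercepts removed), `mse_days2` the mean squared
error in days², and the growth figure says every infant's EMA increased
between the first and last recording.  The selection median counts the
features the backward elimination kept per cross-validation fold — on
this synthetic cohort a couple of timing/amplitude features carry almost
all the age information, so the selected sets are far smaller than they
would be on clinical EEG.  Numbers above are from the run shown
(seed 1); they vary slightly with the seed.

A command-line wrapper for batch use (EDF + manifest in, CSV/JSON out)
is in `inst/scripts/ema.R` with `simulate`, `features`, `crossval` and
`evaluate` subcommands.

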