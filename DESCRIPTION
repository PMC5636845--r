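Package: neoEMA
Title: EEG Maturational Age Estimation for Preterm Infants
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates a functional brain age (the EEG maturational age, EMA)
    from multichannel neonatal EEG. Raw referential recordings are band-pass
    filtered, resampled to 64 Hz, re-montaged to a standard bipolar layout and
    cut into overlapping epochs. Spontaneous activity transients (SATs) are
    detected with a smoothed nonlinear energy operator, amplitude-based
    artefact rules exclude contaminated epochs, and 23 computational features
    (envelope and range-EEG percentiles, band powers, SAT timing statistics
    and an interhemispheric activation synchrony index) are extracted from
    both the full epoch and a low-SAT% (quiet-sleep proxy) segment, giving 46
    features per epoch. Features are mapped to age with support vector
    regression inside a leave-one-infant-out cross-validation with backward
    feature selection, and the resulting age estimates are evaluated with
    repeated-measures mixed models, error metrics, serial-growth analysis and
    reduced-montage comparisons. A synthetic cohort generator with known
    ground truth supports development and testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    lme4,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Electrophysiology, Regression, FeatureExtraction, Preprocessing
RoxygenNote: 7.3.3
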