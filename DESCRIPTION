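Package: pdembed
Title: Visualization and Classification of Parkinsonian Motor Behavior
    with Nonlinear Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating neurologically healthy subjects from
    Parkinson's disease patients treated with levodopa or deep brain
    stimulation, using multichannel inertial and electromyographic
    recordings of standardized motor tasks. Provides a seeded synthetic
    cohort simulator with calibrated intra-subject variability,
    Hilbert-based preprocessing (instantaneous amplitude and frequency)
    with twelve time-domain features per channel, z-score standardization
    and stratified train/test splitting, two-dimensional embeddings by
    principal component analysis, Sammon's mapping and t-distributed
    stochastic neighbor embedding implemented from their defining
    objectives, a parametric out-of-sample extension (variance-preserving
    projection plus a Bayesian-regularized regression network), one-vs-all
    Gaussian-kernel support vector classification with leave-one-out
    cross-validation, ROC/AUC with bootstrap confidence intervals,
    Kolmogorov-Smirnov comparisons, and an exhaustive hyperparameter grid
    scored by the quality ratio of cross-validated and test success rates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    readxl,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
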