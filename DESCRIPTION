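Package: oxiscreen
Title: Multidimensional Pulse-Oximetry Screening for Obstructive Sleep Apnea
Version: 0.1.0
Authors@R:
    person("Oxiscreen", "Developers", email = "oxiscreen@example.org",
           role = c("aut", "cre"))
Description: Extracts an eight-parameter nocturnal oximetry profile
    (mean and minimum SpO2, oxygen desaturation index, T90, ST90,
    hypoxic burden via rainwater-trapping event delineation, attention
    entropy, and ultradian-band Lomb-Scargle spectral power) from 1 Hz
    SpO2 recordings, and runs a reproducible screening-model pipeline:
    z-score scaling, SMOTE confined to training folds, stratified
    5-fold cross-validation over six classifier families, exhaustive
    1-4 parameter subset search, external validation, restricted
    cubic-spline nonlinearity tests, additive feature attribution, and
    sex/age subgroup analyses. Includes a synthetic cohort generator so
    the whole pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    splines,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
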