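Package: synergyscore
Title: Synergy and Sensitivity Scoring for High-Order Drug Combinations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scores drug combination experiments of any order against the
    four major non-interaction reference models (highest single agent,
    Bliss independence, Loewe additivity, and zero interaction potency)
    on full-factorial dose-response matrices, and quantifies overall
    treatment efficacy with the combination sensitivity score (CSS).
    Monotherapy and conditional dose-response relationships are modelled
    with the four-parameter log-logistic curve. Bootstrap resampling of
    replicate measurements yields dose-level confidence intervals and
    block-level empirical P values for every synergy score. A synergy
    barometer places observed responses against all four model
    expectations on one percent-inhibition scale, synergy-sensitivity
    plot coordinates support combination prioritization, and classical
    multidimensional scaling of dose-rank vectors lays out synergy
    landscapes for combinations of three or more drugs. Includes a
    synthetic data generator with known ground truth and a command-line
    interface for batch reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'data_model.R'
    'curve_fit.R'
    'fixtures.R'
    'synergy_models.R'
    'landscape_layout.R'
    'stats_bootstrap.R'
    'sensitivity_css.R'
    'cli.R'
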