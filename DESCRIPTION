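Package: popwise
Title: Population-Wise Error Rate Control for Trials with Overlapping Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation and control of the population-wise error rate (PWER)
    for clinical trials that test treatment policies in multiple, possibly
    overlapping target populations. Provides critical-value calibration and
    adjusted p-values under multivariate normal or t joint null distributions,
    strata-wise family-wise error reports and bounds, design calculators for
    two overlapping populations (independent samples and shared-control
    single-trial scenarios) with sample-size inflation curves, the
    subset-selection multiple-testing procedure for umbrella trials with a
    performance simulator, a robustness study for estimated stratum
    prevalences, simultaneous confidence intervals dual to the PWER test, and
    a seeded subject-level trial simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    mvtnorm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
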