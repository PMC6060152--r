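Package: sleepmetab
Title: Sleep/Wake State Analysis of Brain Microdialysis Metabolomics Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, reusable pipeline for untargeted metabolomics time
    series collected by brain microdialysis across sleep, spontaneous wake and
    enforced wake. Implements baseline z-scoring against a treadmill reference
    window, outlier flagging, behavioral-state sample exclusion, hourly
    coarse-graining and two-tier imputation; single-linkage clustering of
    unknown spectral features by exact mass and retention time; per-analyte
    linear mixed-effects model selection with likelihood-ratio tests and an
    explicit state-specificity verdict; classification of sleep-decline
    patterns across early, late and recovery sleep; partial least squares
    discriminant analysis with variable-importance-in-projection scores;
    l2-penalized multinomial logistic classification under repeated stratified
    mouse-level cross-validation with permutation significance testing; and
    Pearson correlation of metabolite levels with EEG band power under
    Benjamini-Hochberg control. A synthetic-cohort generator emulating the
    three-arm study design with known ground truth supports validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
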