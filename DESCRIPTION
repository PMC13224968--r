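Package: deepweibull
Title: Neural-Network Weibull Accelerated Failure Time Models for Genetic
    Survival Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric survival modelling for time-to-onset studies with
    high-dimensional genetic predictors. Fits Weibull accelerated failure
    time (AFT) models in which the per-subject scale parameter is produced
    either by a linear predictor or by a small feedforward neural network
    with SoftPlus hidden layers, trained by censored maximum likelihood.
    Includes SNP carrier-indicator and APOE genotype encoding, VCF variant
    extraction, stratified cross-validation with Harrell's concordance
    index and the IPCW integrated Brier score, exact and permutation-
    sampling Shapley-value attribution of model predictions, SHAP-ranked
    incremental feature selection, and a synthetic SNP cohort simulator
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
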