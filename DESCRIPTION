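Package: metfa
Title: Factor Analytic Mixed Models for Multi-Environment Trial Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Single-stage genomic selection for multi-environment trial (MET)
    datasets using factor analytic linear mixed models. Implements the full
    family of genotype-by-environment variance structures -- identity, diagonal,
    compound symmetry, main effects plus diagonal, factor analytic with simple
    (FAM) or generalised (FA) main effects, random regressions on known
    environmental covariates (rreg1, rreg2, FAR) and the integrated factor
    analytic model (IFA) whose common factors combine known covariates with
    latent directions orthogonal to them -- fitted by average-information REML
    with a marker-derived genomic relationship matrix. Includes singular value
    decomposition rotation of loadings to principal axes, variance-explained
    summaries, genotype regression plots, leave-one-environment-out
    cross-validation, prediction into future environments from their covariates,
    and a synthetic MET generator with a truth record for parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
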