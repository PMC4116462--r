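Package: flymetab
Title: Factorial Analysis of Untargeted Metabolomics in Inbred Fly Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for untargeted LC-MS feature tables from
    factorial age-by-sex-by-genotype designs in inbred Drosophila panels.
    Provides a synthetic-data generator with planted effects and known
    variance components, a six-step quality-control cascade
    (signal-to-noise filtering, log transform, sex-wise missingness
    filtering, correlation-weighted least-squares imputation, mass-charge
    filtering, sample centering), per-feature fixed-effect factorial models
    with per-factor Benjamini-Hochberg false discovery control and
    direction labels, intraclass-correlation heritability screening with
    REML and method-of-moments estimators, NIPALS partial least squares
    regression and sparse PLS discriminant analysis with stratified
    cross-validation, classification error rates and permutation nulls,
    and a simplified one-step mass-charge adduct annotation plus pathway
    enrichment stage with a permutation null over feature selections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nlme,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    lmtest,
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
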