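Package: rixmm
Title: Multiple-Membership Mixed Models for Recombinant Inbred Intercross Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Variance-component analysis of phenotypes measured on F1 hybrids
    of recombinant inbred strains (RIX panels), where every animal inherits
    from two parental strains and therefore belongs to two levels of the
    strain random effect.  Provides construction of multiple-membership
    random-effect design matrices, restricted maximum likelihood (REML)
    estimation of variance components, boundary-corrected likelihood ratio
    tests, heritability partitioning, best linear unbiased predictors (BLUPs)
    with prediction intervals, extreme-strain flagging, cross-phenotype
    strain-effect correlations, and a synthetic-data generator that emulates
    a placebo-controlled drug study in a quasi-loop RIX design for
    parameter-recovery and calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    ggplot2,
    optparse,
    Matrix
Config/testthat/edition: 3
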