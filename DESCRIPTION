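Package: ossage
Title: Transition Analysis for Forensic Age Estimation from Clavicle
    Ossification Stages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical pipeline for MRI-based forensic age estimation
    from the ossification stage of the medial clavicular epiphysis.
    Resolves multi-rater stage readings into consensus stages by majority
    vote with adjudication, computes descriptive and side-comparison
    statistics, chance-corrected inter- and intra-rater agreement (Fleiss'
    kappa, Cohen's kappa, Krippendorff's alpha, with and without ordinal
    weights), fits a cumulative probit transition-analysis model of stage
    group on age by maximum likelihood, inverts it into normed likelihood
    curves with point predictions and 95 percent prediction intervals,
    classifies minors versus adults, and evaluates predictive performance
    through cross-validation and test-set constellations. A synthetic
    cohort generator with the same statistical structure makes every step
    testable without access to study data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
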