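Package: hhsurvey
Title: Design, Simulation and Evaluation of Two-Stage Household Health Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and evaluating household health surveys that use
    stratified sample-size planning and two-stage cluster sampling with
    probability proportional to size (PPS). Implements person-per-household
    sample-size planning with non-response inflation, construction of
    primary sampling units (PSUs) from census tracts under a size-homogeneity
    constraint, systematic PPS selection of PSUs followed by systematic
    household sampling with a fixed second-stage fraction (self-weighting
    designs), simulation of household fieldwork under a three-visit protocol
    with refusal and absence non-response, and design-based estimation of
    proportions with Taylor-linearized (ultimate-cluster) variances,
    coefficients of variation, design effects and predictive mean matching
    imputation. A synthetic census-frame generator with controllable
    intra-cluster correlation supports end-to-end Monte-Carlo evaluation of
    a design's precision and design effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
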