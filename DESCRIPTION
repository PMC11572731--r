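Package: prlmediate
Title: Causal Mediation of Race-Related Multiple Sclerosis Disability by
    Paramagnetic Rim Lesion Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying how the percentage
    of paramagnetic rim lesions (PRLs) mediates the disparity in Expanded
    Disability Status Scale (EDSS) scores between Black-American and
    White-American multiple sclerosis cohorts. Provides a calibrated synthetic
    patient-cohort generator (linear-Gaussian and overdispersed lesion-count
    modes), table-one style two-group comparison statistics, the three linear
    models of the mediation design, product-of-coefficients ACME/ADE estimation
    with nonparametric percentile-bootstrap inference, and a
    sequential-ignorability sensitivity analysis over the mediator-outcome
    residual correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
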