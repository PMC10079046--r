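Package: sdgmort
Title: Small-Area Estimation and SDG Projection of Under-5 and Neonatal Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates province-level under-5 (U5MR) and neonatal (NMR) mortality
    rates from heterogeneous, incomplete data sources (death registration with
    incompleteness, summary and complete birth histories) by Bayesian model
    averaging of a Gaussian-process regression stage model with a covariate
    mixed-model mean and a spatiotemporal stage model with Besag-York-Mollie
    spatial, second-order random-walk temporal and interaction components.
    Derives NMR from U5MR through a quadratic log-log relation with
    province-year effects truncated so NMR never exceeds U5MR, and projects
    NMR to 2030 under five annual-rate-of-reduction scenarios against the
    SDG 3.2 threshold of 12 deaths per 1,000 live births. Includes a synthetic
    panel generator that emulates the statistical structure of the source data
    for parameter-recovery testing, direct and indirect birth-history
    estimators, data-quality gates, ensemble scoring, reporting metrics and a
    seeded end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    lme4,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
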