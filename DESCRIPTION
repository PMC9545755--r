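Package: driftshift
Title: Waterfowl Distribution Shifts Around Extreme Winter Weather from
    Citizen-Science Checklists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for measuring short-interval distribution
    shifts of wintering waterfowl from eBird-style citizen-science
    checklists and validating them against GPS telemetry. Implements
    semi-structured checklist filtering with a per-rule attrition audit,
    abundance-weighted positional centroids, a signed north-south
    early-to-late shift statistic on the great circle, classification of
    severe-February years from gridded temperature-anomaly fields, a
    Bayesian hierarchical linear model of shift distances with year random
    intercepts fit by MCMC (via JAGS), marginal posterior summaries per
    foraging-strategy-by-event cell, and a synthetic-data generator with
    known ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    geosphere,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
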