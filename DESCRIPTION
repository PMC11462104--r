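Package: ctmccohort
Title: Continuous-Time Markov Chain Analytics for Chronic-Disease Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds continuous-time Markov chain (CTMC) disease-progression
    models from minimal longitudinal episode records (patient identifier,
    episode name, day from baseline). Composes same-day multimorbidity
    episodes into composite Markov states, merges consecutive duplicate
    episodes, estimates jump and infinitesimal generator matrices from
    transition counts and holding times, computes time-variant transition
    probabilities P(t) = expm(Q t), and produces progression-pattern tables,
    state-mix forecasts and stratified cohort comparisons. A built-in cohort
    simulator with exponential holding times makes every stage testable
    without access-restricted registry data.
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
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
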