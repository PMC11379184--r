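Package: opioidwaves
Title: Bayesian Multiple-Changepoint Modelling of State-Level Opioid
    Overdose Death Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies drug-overdose deaths into drug-involvement
    categories from ICD-10 multiple-cause codes, aggregates them to a
    state-by-year-by-drug lattice, and fits a Bayesian multivariate
    multiple-changepoint Poisson model in which piecewise-constant death
    rates are segmented by a centered autologistic changepoint process
    with regional random effects. Includes a synthetic-data generator
    with planted regimes for recovery studies, a Metropolis-within-Gibbs
    sampler with collapsed conjugate indicator updates, posterior
    summaries (median rates, relative-risk direction flags, changepoint
    log odds, wave-onset years), diagnostics, figures, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    MASS,
    ggplot2,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
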