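Package: countyswing
Title: County-Level Mortality Change and Presidential Vote Swing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Ecological analysis tools linking county-level changes in
    age-adjusted death rates to changes in US presidential voting.
    Implements the net Republican percentage gain outcome, direct age
    standardization of county death rates, multilevel left-censored
    Bayesian imputation of suppressed rare-cause death counts with
    Rubin's multiple-imputation combining rules, state-clustered group
    comparisons, a multivariable random-slope mixed model with a
    piecewise population effect, sensitivity analyses, and swing-state
    counterfactual arithmetic. A synthetic-data generator reproduces the
    hierarchical structure of the county panel so the full pipeline runs
    and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    rjags,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
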