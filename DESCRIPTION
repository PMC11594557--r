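Package: gmediate
Title: Interventional Mediation Analysis for Time-Varying Exposures by
    Parametric G-Computation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates interventional overall and indirect effects of a
    time-varying binary exposure on mortality through multiple chronic-disease
    mediators, using Monte Carlo simulation-based parametric g-computation on
    discrete person-period data. Provides construction of person-period panels
    from event records with carry-forward (chronicity), absorbing death and
    censoring conventions; per-interval logistic models for death and disease
    onset with forward-backward stepwise AIC selection; forward simulation of
    counterfactual exposure and mediator-shift scenarios; effect decomposition
    with cluster (person-level) percentile bootstrap confidence intervals; and
    a synthetic-cohort generator from a fully known structural causal model
    with exact enumeration and large-sample simulation oracles for validating
    the estimation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
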