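Package: maintCEA
Title: Cost-Effectiveness Modelling of Switch Maintenance Therapy in Advanced Gastric Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for trial-based cost-effectiveness analysis of switch
    maintenance therapy in advanced HER2-negative gastric and
    gastroesophageal junction cancer. Reconstructs pseudo
    individual-patient data from digitized Kaplan-Meier curves and
    numbers at risk, fits a fifteen-family zoo of parametric and flexible
    survival models (including fractional polynomials, Royston-Parmar
    splines, a Weibull mixture-cure model and a penalized
    piecewise-exponential smoother) with AIC/BIC selection, runs a
    three-state Markov cohort model over a ten-year horizon with
    body-surface-area based drug costing, and quantifies uncertainty by
    one-way and probabilistic sensitivity analysis, cost-effectiveness
    acceptability curves and threshold price search. A synthetic trial
    generator makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    flexsurv,
    mgcv,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
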