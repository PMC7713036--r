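Package: stochmsm
Title: Stochastic Treatment Regimens and Inverse-Probability-Weighted
    Discrete-Time Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Emulates target trials of treatment-duration regimens from
    longitudinal dispensing and covariate data.  Provides a synthetic cohort
    generator with treatment-confounder feedback and rare terminal events,
    quarterly proportion-of-days-covered (PDC) exposure classification with
    stockpiling rules, stochastic discontinuation regimens with dual-arm
    person-time contribution, stabilized and truncated inverse-probability
    weights for treatment and censoring, saturated marginal structural model
    estimation of counterfactual discrete-time hazards, survival, cumulative
    risk and risk differences, a bootstrap test for the difference in areas
    under survival curves, and a direct-intervention Monte Carlo oracle for
    the true counterfactual risks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
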