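Package: iusmmt
Title: Intersection-Union Survival Mixture-Adjusted Mediation Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene-centric mediation analysis for censored survival outcomes
    with multiple DNA-methylation CpG sites as exposures and one gene
    expression level as the mediator.  Stage tests are a variance-component
    score test under a linear mixed model (methylation to expression) and a
    Wald test for the expression effect under a Cox model with ridge-penalized
    CpG random effects (expression to survival).  Overall mediation
    significance uses the maximum of the two stage p-values, calibrated
    against an estimated three-component mixture null distribution so that
    family-wise error or false discovery rates are controlled without the
    conservativeness of the naive intersection-union test.  Includes a
    kernel-machine total-effect test, a reverse multivariate score test that
    screens passenger methylation events, and a simulator for correlated CpG
    blocks, mixed-model expression and Weibull survival with random censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    mgcv,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
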