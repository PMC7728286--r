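Package: collinobs
Title: Observer Models for Collinearity Judgment Under Sensory Uncertainty
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and Bayesian analysis of a two-task psychophysics
    experiment on contour integration: a collinearity judgment task and a
    Vernier-style height judgment task in which sensory uncertainty is
    manipulated trial-by-trial via retinal eccentricity. Provides generators
    for the tasks' stimulus statistics, a family of observer decision models
    (Bayes-optimal, fixed-criterion, linear heuristic, and suboptimal Bayesian
    variants with noise/width mismatch and decision noise), exact response
    probabilities by adaptive quadrature, posterior inference by coordinate-wise
    slice-sampling MCMC with Gelman-Rubin diagnostics, model comparison by
    Pareto-smoothed importance-sampling leave-one-out cross-validation (PSIS-LOO)
    and hierarchical random-effects Bayesian model selection with protected
    exceedance probabilities, plus suboptimality/efficiency analysis and
    parameter/model recovery harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
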