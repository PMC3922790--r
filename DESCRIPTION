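Package: bayesmisclass
Title: Bayesian Correction of Exposure Misclassification in Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probabilistic bias analysis of retrospectively reported
    binary exposures in case-control studies. Implements a jointly estimated
    three-part Bayesian logistic model that treats true exposure as latent and
    the retrospective report as error-prone with case/control-specific
    sensitivity and false-positive probability, sampled by a data-augmentation
    Markov chain Monte Carlo algorithm (exact Gibbs step for the latent
    exposure, adaptive random-walk Metropolis for the regression coefficients).
    Also provides the misclassification-naive estimators (crude,
    matching-factors-only and fully adjusted frequentist logistic regressions,
    consistency-stratified and per-exposure-window models, and a naive Bayesian
    logistic model), credible and confidence limit ratios,
    sensitivity/false-positive-probability scenario grids in the four
    differential-recall groups, and a synthetic case-control cohort generator
    emulating a pediatric neurodevelopmental study with maternally reported
    household pesticide exposure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    ggplot2,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
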