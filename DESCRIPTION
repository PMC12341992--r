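Package: relugof
Title: Goodness-of-Fit Significance Tests for Covariates via Deep ReLU
    Network Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Significance testing for input features in nonparametric
    regression using goodness-of-fit statistics built on sample splitting
    and feed-forward ReLU neural network estimators. One half of a random
    split fits the regression without the tested covariates, the other half
    fits it with all covariates; the standardized difference of the two
    split-specific mean squared errors is asymptotically standard normal,
    giving a two-sided Z-test. Includes the network fitting machinery
    (mini-batch gradient descent with dropout, compiled backend), sample-size
    indexed architecture rules with a growth-condition diagnostic, a Monte
    Carlo harness for empirical type-I error and power against a linear-model
    t-test baseline, and a gene-expression association screening pipeline
    with a synthetic expression generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
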