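Package: circlequest
Title: Ideal-Observer Analysis of Active Information Sampling in the Circle
    Quest Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing active information-sampling behaviour in the
    Circle Quest hidden-circle localisation task. Implements a grid-based
    Bayesian ideal observer that tracks the posterior over hidden-circle
    centres and converts it into expected-error (EE) maps, an exponential
    uncertainty-decay model yielding a per-participant information
    extraction rate, expected-value curves with a softmax stopping rule and
    the optimal sample count, behavioural markers (inter-sampling interval,
    over-sampling), an affective-burden principal component with
    permutation-based group contrasts and partial Spearman correlations, a
    synthetic cohort and passive-offer generator, and a reproducible
    simulate-fit-report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
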