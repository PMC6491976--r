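Package: maswdesign
Title: Design and Optimization of Multiarm Stepped-Wedge Cluster Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluate and optimize multiarm stepped-wedge cluster randomized
    trial designs analyzed with a linear mixed model with known variance
    components. Computes the generalized-least-squares covariance matrix of the
    treatment effect estimators for any allocation matrix, individual and
    combined (disjunctive) power for one-sided Wald tests with optional
    Bonferroni correction, D-, A- and E-optimality criteria, and weighted
    cost-efficiency admissibility scores. Optimal allocation matrices are found
    by exhaustive enumeration over constrained design spaces (using symmetry
    reduction over cluster sequences) or by a cross-entropy stochastic search.
    A Monte-Carlo simulator provides an independent check of the analytic power
    calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mvtnorm,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
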