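Package: IRTreeScore
Title: Score-Based Heterogeneity Tests and Partitioning for IRTree Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multidimensional item response tree (IRTree) models for six-point
    Likert responses with nonmoderate and extreme response-style dimensions,
    estimated by marginal maximum likelihood with Gauss-Hermite quadrature.
    Provides per-person score contributions, decorrelated cumulative score
    (empirical fluctuation) processes along person covariates, score-based
    parameter-invariance tests for metric, ordinal and unordered categorical
    covariates (double-maximum, Cramer-von Mises, maximum Lagrange multiplier,
    their ordinal variants and the unordered LM test) with analytic or simulated
    p-values, a model-based partitioning algorithm that locates the covariate
    value at which parameters change, and a simulation harness for Type-I error,
    power and cutpoint-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, graphics, tools, jsonlite, yaml, pracma, optparse
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
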