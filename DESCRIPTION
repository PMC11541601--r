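Package: screendif
Title: Measurement Invariance and Screening Accuracy for Diagnostic
    Interview Gate Questions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing whether the dichotomous screening ("gate")
    rules of lay-administered psychiatric diagnostic interviews measure the
    underlying internalising liability equivalently across population
    subgroups. Implements a one-factor confirmatory factor analysis for
    binary indicators via tetrachoric correlations, a two-parameter logistic
    item response model estimated by Bock-Aitkin marginal maximum likelihood,
    multigroup estimation with equality constraints, iterative purified-anchor
    detection of differential item functioning (DIF) with Benjamini-Hochberg
    adjusted likelihood-ratio tests, and quantification of the impact of DIF
    on screening sensitivity, specificity and classification rate at a
    sum-score cut-point via the test characteristic curve and the
    Lord-Wingersky summed-score recursion. A synthetic-data generator with
    known item parameters and injectable DIF supports simulation studies and
    end-to-end pipeline checks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
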