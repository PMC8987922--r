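Package: adamant
Title: Adaptive Mantel Testing with Ridge-Penalized Kernels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Permutation-based adaptive Mantel association tests between a
    high-dimensional design matrix and a univariate response, using the
    ridge-penalized linear kernel. The ridge penalty is tuned per permutation
    by generalized or leave-one-out cross-validation over a singular-value
    thresholded interval that may extend to negative penalties, with an
    optional Gamma method-of-moments approximation to the permutation null.
    Includes spectral shortcuts for the score statistics and cross-validation
    criteria, Monte-Carlo drivers for Type-I-error and power experiments, and
    a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
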