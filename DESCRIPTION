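Package: ebmf
Title: Empirical Bayes Matrix Factorization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits low-rank matrix factorizations Y ~ L'F + E in which the
    prior distributions of loadings and factors are estimated from the data
    by empirical Bayes. A variational approximation reduces every update to
    an empirical Bayes normal-means problem, so the amount of shrinkage (and
    hence sparsity) of each loading and each factor is tuned automatically.
    Includes greedy and backfitting multi-factor fitting with automatic rank
    selection, missing-data imputation, point-normal and scale-mixture-of-
    normals prior families, simulation designs and evaluation metrics, and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
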