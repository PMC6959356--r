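Package: csea
Title: Cell Set Enrichment Analysis for Ranked Single-Cell Signature Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects whether cells from one condition concentrate at an extreme
    of a per-cell transcriptional signature score, independently of any
    clustering. Implements VISION-style per-cell signature scoring from
    normalized log expression, a weighted Kolmogorov-Smirnov running-sum
    enrichment score over ranked cells with leading-edge reporting, label
    permutation and expression-matched random geneset null models with
    Benjamini-Hochberg screening, and simulation-based power and calibration
    evaluation (Gaussian-mixture cell states and a negative-binomial count
    model driven by a continuous latent state).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
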