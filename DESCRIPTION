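Package: drscore
Title: Drug Regulatory Scores from Perturbation Expression Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds drug treatment expression signatures from treated
    versus control log2 expression profiles, scores tumor or cell-line
    samples against those signatures with a foreground/background
    running-sum statistic normalized by gene permutation, and runs the
    downstream analyses that a pathway-activity study needs: survival
    stratification at a score cutpoint, univariate Cox screening,
    correlation with ordinal clinical scores, drug-sensitivity (IC50)
    correlation screens with false-discovery control, and random-forest
    classification of treatment-response labels. Includes a synthetic
    cohort generator with known latent pathway activity so every stage
    is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
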