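Package: guidelm
Title: Interpretable Linear Models for CRISPR-Cas9 Guide Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prediction of CRISPR-Cas9 guide RNA on-target efficiency from
    30-nucleotide target sequences using interpretable linear-family models.
    Provides position-specific and global sequence featurization, fitting of
    ordinary least squares, fractional-logit and logistic models for U6- and
    T7-expressed guides, multi-step feature selection, ranking evaluation via
    Spearman correlation and normalized discounted cumulative gain, exact
    additive feature-effect interpretation of every prediction, seeded
    synthetic-data generation from known ground-truth models, and a
    command-line interface for batch scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    glmnet,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
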