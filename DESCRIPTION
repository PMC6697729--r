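Package: subspectra
Title: Cancer Subtype Classification from Functional Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Transforms per-sample gene expression profiles into functional
    spectra of gene-set enrichment scores (a weighted running-sum statistic
    over a ranked fold-change list) and trains a feedforward neural network
    on the spectra to call molecular subtypes, with an explicit
    UNCLASSIFIED outcome for low-confidence samples. Because spectra are
    defined on gene sets rather than individual genes, trained classifiers
    tolerate missing genes across expression platforms; a single-sample
    predictor rescales one profile to a cohort reference by linear
    regression so individual patients can be classified. Includes
    evaluation metrics, deep-feature interpretation tools, a synthetic
    cohort generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    cluster,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
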