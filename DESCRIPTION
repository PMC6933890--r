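Package: famhx
Title: Family History Information Extraction from Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts family history information (family members with their
    side-of-family attribute, and clinical observations) from free-text
    patient notes. Provides three IOB2 tag schemes that optionally encode
    the normalized family-member name and the side of family inside the
    labels, a neural sequence labeler (character-level CNN, bidirectional
    LSTM over word and handcrafted feature embeddings, linear-chain CRF
    inference) with a compiled core, a classical feature-based CRF
    baseline, rule-based normalization of member mentions and resolution
    of the side attribute, the document-level partial-match evaluation
    protocol used by the BioCreative/OHNLP family-history task, and a
    synthetic-corpus generator for fully reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
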