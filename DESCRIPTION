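Package: jpdeid
Title: De-Identification of Japanese Clinical Free Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and removing protected health information
    (PHI) from Japanese electronic health records and pathology reports.
    Implements three span taggers over a five-type tag set (age, sex, time,
    hospital, person): a deterministic rule-based tagger built on a keyword
    and suffix lexicon, a linear-chain conditional random field with five
    token-level feature families, and a BiLSTM-CRF combining character-level
    and word-level embeddings. Includes an inline-tag corpus format with
    IOB2 conversion, strict span-level precision/recall/F1 evaluation with
    k-fold cross-validation and inter-annotator agreement, a synthetic
    corpus generator emulating three clinical text styles, and surrogate
    replacement of masked placeholder characters with dummy names.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
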