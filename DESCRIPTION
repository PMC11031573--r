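Package: icdvec
Title: Embedding-Based ICD-10 Coding of German Clinical Diagnosis Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Infers ICD-10 codes from free-text German diagnosis phrases by
    nearest-centroid search in a word-embedding space. Provides phrase-aware
    normalization of clinical German (umlaut transliteration, number and
    punctuation filtering, optional compound splitting), a deterministic
    skip-gram-with-negative-sampling embedding trainer, thesaurus-driven
    placement of one centroid per ICD-10 code, cosine nearest-centroid
    inference with distance thresholding, and two-level evaluation (exact
    code versus 3-character superordinate group). Ships a synthetic-world
    generator so the whole pipeline can be exercised and validated without
    access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stringr,
    tibble,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
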