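Package: lcscoder
Title: Automatic ICD-10 Diagnosis Coding via Semantic Longest Common
    Subsequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps free-text clinical diagnosis names to standardized
    ICD-10 codes from a standard diagnosis library. Implements
    lexicon-based forward-maximum-matching word segmentation with
    stop-word filtering and negation retention, a semantic longest
    common subsequence (LCS) dynamic program in which tokens match when
    their synonym-ontology similarity exceeds a threshold, the LCS-ratio,
    twofold T-LCS and weighted W-LCS string similarity measures, a
    confidence-thresholded code-assignment policy, and
    precision/recall/F-score evaluation with threshold sweeps on
    reproducible synthetic benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    Rcpp,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
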