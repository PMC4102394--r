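Package: gkmkit
Title: Gapped k-mer String Kernels for Regulatory Sequence Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of regulatory DNA sequences (enhancers,
    transcription-factor bound regions) with gapped k-mer string kernels.
    Kernels are assembled from pairwise l-mer mismatch profiles, computed
    either by direct all-pairs comparison with bitwise Hamming counting or
    by a k-mer tree depth-first traversal with optional mismatch
    truncation. A unified distance-indexed weight scheme also reproduces
    the wildcard and mismatch string kernels, and a pseudo-inverse filter
    yields smoothed ("robust") l-mer count estimates used by a
    Naive-Bayes classifier. Includes support-vector-machine training on
    precomputed kernels, de novo position weight matrix extraction from
    ranked k-mer weights, ROC/PR/cross-validation evaluation, and a
    seeded planted-motif benchmark generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    Matrix,
    kernlab,
    Biostrings,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    generics,
    rlang,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    pracma,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
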