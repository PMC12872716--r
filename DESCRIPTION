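Package: hexbias
Title: Homoeolog Expression Bias and Biomarker Discovery in Hexaploid Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing subgenome expression dynamics in hexaploid
    wheat RNA-seq time courses. Classifies homoeolog triads into seven
    expression-bias categories (dominant, suppressed, balanced) from relative
    TPM shares, quantifies category stability across developmental stages and
    between genotypes, scans chromosomes for regions enriched in concordant
    differential expression by Gaussian kernel smoothing with a permutation
    null, and selects discriminative biomarker genes with a nearest shrunken
    centroids classifier under repeated cross-validation. Includes a
    negative-binomial simulator of complete hexaploid experiments with planted
    ground truth, so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
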