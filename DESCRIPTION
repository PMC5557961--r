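Package: prowire
Title: Nascent-Transcription Analysis of Pausing, Enhancers and Stress Reprogramming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for strand-specific nascent-transcription
    (PRO-seq-type) data: per-gene quantification of promoter-proximal pausing,
    divergent initiation and gene-body transcription; cross-condition
    normalization anchored on the 3' ends of long genes; a replicate-aware
    negative-binomial differential test with response-class assignment;
    high-resolution refinement of transcribed regulatory elements by support
    vector regression imputation of DNaseI hypersensitivity followed by spline
    peak calling; SVM classification of elements into promoters and distal
    TREs from PRO-seq shape and CpG/GC composition; repertoire comparison
    across conditions; and integration with transcription-factor binding via
    composite profiles, heatmaps and rank statistics. Ships a synthetic-genome
    simulator with full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    e1071,
    pROC,
    readr,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
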