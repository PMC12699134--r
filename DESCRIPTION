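Package: starrmap
Title: Genome-Wide STARR-Seq Enhancer Mapping and Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for quantifying enhancer activity from
    STARR-seq (self-transcribing active regulatory region sequencing) fragment
    libraries. Quantifies RNA-over-input enrichment, calls and filters enhancer
    peaks with an exact binomial window test, classifies enhancer strength by
    changepoint segmentation of ranked activities, annotates chromatin context
    (ATAC-seq, histone marks) and genomic position, scans position weight
    matrices with exact p-values and tests motif enrichment against shifted
    genomic backgrounds, analyzes YY1 motif dosage and designs YY1 motif
    mutagenesis constructs, and prepares summit-centered tiling screens and
    sequence-to-activity window datasets. A synthetic-data generator produces
    toy genomes with planted enhancers so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    GenomeInfoDb,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    purrr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
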