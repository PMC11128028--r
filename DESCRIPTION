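Package: rtchimera
Title: Alignment-Free Detection of Read-Through Chimeric RNAs from RNA-Seq Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects read-through (cis-SAGe) chimeric RNAs from RNA-seq reads
    without alignment. Builds a database of fixed-length exon-exon junction
    sequences from all eligible same-strand neighboring gene pairs, applies a
    cascade of false-positive filters (paralog, flank length, same-isoform,
    exon-match, cross-similarity), expands the database with common-SNP
    variants, searches reads for exact junction matches with a memory-bounded
    multi-pattern scan, and reports breakpoint-annotated candidates after
    ambiguity-aware post-filtering. Includes a seeded synthetic-world generator
    (genome, annotation, paralogs, SNPs, reads) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    dplyr,
    purrr,
    tibble,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
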