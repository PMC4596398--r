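Package: txtile
Title: Genome-Guided Transcript Assembly from Read Tiling and Splice Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A heuristic, annotation-independent transcript assembler for
    short-read RNA-seq. Exons are detected as islands of overlapping read
    alignments above a reads-per-kilobase-of-exon (RPKE) threshold, short exons
    are recovered from splice-junction half-alignments, closely spaced fragments
    are merged, intron-retention noise is adjudicated by a read-density rule,
    and exons are linked through junction edges into single longest-isoform gene
    models. Includes a novel-gene filtering cascade (annotation overlap,
    containment de-duplication, footprint, expression, and genome-similarity
    screens), longest-ORF analysis with codon-length classification, evaluation
    of assembled models against reference transcripts with a seven-category
    discrepancy classification and TSS/TTS offset summaries, and a seeded
    synthetic-genome benchmark that titrates read depth to measure assembly
    accuracy by point of first failure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    IRanges,
    S4Vectors,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
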