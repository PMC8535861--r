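Package: txrefine
Title: Transcriptome-Based Refinement of Genome Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for refining a genome annotation from assembled RNA-seq
    transcript sets. Merges per-sample transcript assemblies into a
    non-redundant transcriptome, classifies each transcript against a
    reference annotation by structural class code (complete intron match,
    novel splice variant, intergenic, antisense, and related categories),
    separates coding from noncoding transcripts with sequence-intrinsic
    open-reading-frame features (ORF length and coverage, the Fickett
    TESTCODE statistic, isoelectric point), positionally classifies
    noncoding RNAs relative to coding genes, groups coding transcripts
    into isoform groups by protein similarity and connectivity, and
    produces a gene-level diff of the new annotation against the old one.
    Includes a synthetic-data generator that plants ground-truth transcript
    structures so the whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    igraph,
    methods,
    stats,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
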