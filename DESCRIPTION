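Package: structrip
Title: Structured-RNA RIP-Seq Analysis with a Planted-Truth Read Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for RNA immunoprecipitation
    sequencing (RIP-seq) experiments that target abundant structured RNAs.
    Provides quality filtering of raw reads, partitioning of alignments into
    uniquely and multiply mapped sets, assignment of multi-mapped reads to
    non-coding RNA classes and ribosomal DNA (rDNA) subregions,
    permutation-based peak calling with Input normalization, IP-versus-Input
    enrichment statistics for small structured RNAs (snoRNAs, scaRNAs),
    per-domain binding-density profiling on the 28S ribosomal RNA,
    differential-expression threshold filtering with hypergeometric gene-set
    overlap tests, and quantification of ribose 2'-O-methylation from RTL-P
    (reverse transcription at low dNTP followed by PCR) RT-qPCR data. A
    deterministic synthetic-data generator plants known binding structure
    (enriched transcripts, rRNA binding windows, genomic peak sites) into
    negative-binomially distributed read counts so every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
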