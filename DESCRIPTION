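Package: serkdup
Title: Tandem SERK Gene Family Analysis: Duplication Dating, Splice Variants
    and Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for characterising small tandemly duplicated
    receptor-like kinase gene families, built around the five-member SERK
    cluster of Medicago truncatula. Provides gene-model handling (FASTA/GFF3,
    intron extraction, transcript splicing, tandem-cluster geometry),
    degenerate-primer arithmetic with in-silico PCR, global pairwise
    nucleotide alignment with affine gap costs, intron-based molecular-clock
    dating of duplication events with UPGMA event-order inference,
    splice-variant classification with ORF and protein prediction,
    SERK-diagnostic motif scanning with ProtParam-style protein statistics,
    efficiency-corrected qPCR relative quantification (Pfaffl), and seeded
    synthetic-data generators that emulate the study conditions end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    BiocGenerics,
    S4Vectors,
    GenomicRanges,
    ape,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
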