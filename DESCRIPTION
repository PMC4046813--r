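Package: tsskit
Title: Strand-Specific Transcriptome Annotation and Transcription Start
    Site Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytics for strand-specific RNA-seq annotation of compact
    eukaryotic (fungal) genomes: per-locus sense/antisense read counting and
    RPKM summaries, coverage-merge transcribed-fragment discovery with
    gene-count extrapolation, splice-junction extraction and classification,
    alternative-splicing pattern detection (exon skipping, intron retention),
    positional classification of natural antisense transcription, 5' read-head
    transcription start site calling with a mirror-symmetrized bootstrap
    confidence-interval-length sharpness metric, and promoter composition and
    motif enrichment against a third-order Markov background. Includes a
    synthetic-data generator that emulates the statistical structure of the
    real libraries so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
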