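Package: tipseq
Title: Digital Quantification of Organelle RNA Editing and Intron
    Retention from Targeted Nanopore Amplicons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for Target-Indexed-PCR (TIP) sequencing:
    multiplexed, barcoded long-read amplicon sequencing of organelle
    transcripts.  Demultiplexes pooled nanopore reads by 8-nt primer
    barcodes with strand reorientation, aligns reads to a barcoded
    pseudo-genome with a banded affine-gap semi-global aligner, counts
    cytidine and thymidine calls at known C-to-U editing sites to compute
    per-replicate editing efficiencies, detects intron-retaining
    (unspliced) transcript isoforms by CIGAR insertion scanning with local
    alignment of inserts against the intron reference, and summarises
    replicates with Welch unequal-variance t-tests.  A seeded read
    simulator with full ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
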