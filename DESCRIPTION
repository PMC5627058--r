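Package: meripr
Title: Comparative MeRIP-Seq Analysis of m6A Methylomes Between Two Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparative m6A-seq (MeRIP-seq) analysis of
    two tissues with two biological replicates each: FASTQ read quality control
    (adapter removal, 3' quality trimming, length and quality retention
    filters), FPKM expression with an expressed-gene threshold, IP-versus-input
    sliding-window peak detection with exact enrichment tests under
    Benjamini-Hochberg FDR control, replicate peak concordance, classification
    of peaks and genes as commonly or tissue-specifically methylated, metagene
    peak-occupancy profiles, a five-region peak topology classifier, k-mer
    motif enrichment, and gene-set overlays. A seeded synthetic-data generator
    produces annotation, sequence, ground-truth peaks and simulated IP/input
    reads with the statistical structure the analysis assumes, so every stage
    is testable without access to raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
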