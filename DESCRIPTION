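Package: ticfinder
Title: Detection of Transcription-Induced Chimeras in Single-End RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects readthrough gene fusions (transcription-induced
    chimeras, TICs) in short single-end RNA-Seq reads by two complementary
    strategies: targeted alignment of reads to a database of artificial
    exon-exon junction sequences with multi-stage consistency, homology and
    shifted-junction false-discovery-rate filtering; and classification of
    split or spliced genomic alignments into readthrough, intervening-exon
    (TICIE), long-range, scrambled, inversion and translocation categories.
    Downstream analyses assemble chimeric transcripts, predict their coding
    region, frame and nonsense-mediated-decay status, compare preserved
    protein domains, and summarise gene expression (RPKM) and readthrough
    splicing efficiency. A seeded simulator generates toy genomes,
    annotations and reads with planted events for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
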