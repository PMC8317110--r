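Package: isomirs
Title: Deterministic and Exhaustive isomiR Profiling from Small RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and quantifies microRNA isoforms (isomiRs) directly from
    adapter-trimmed short RNA-seq reads using precomputed exact k-mer lookup
    tables instead of a read aligner. An offline build stage expands miRNA
    precursors with genomic flanks, enumerates every candidate isomiR of 18-26
    nucleotides, locates each candidate exhaustively in the genome to tag it as
    exclusive to miRNA-space or ambiguous, annotates overlap with RepeatMasker
    repeat classes, and precomputes variant-containing isomiRs from catalogued
    SNPs and somatic mutations. The online stage collapses reads to a frequency
    table, resolves each distinct sequence against the tables with a 3'
    non-templated-addition rescue, and quantifies without double counting.
    Results carry offset labels, genome-anchored labels and sequence-derived
    "license plate" identifiers, and are written as tab-separated text, mirGFF3
    and a self-contained HTML overview. A synthetic mini-genome generator and
    read simulator provide a download-free test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stringr,
    tibble,
    tidyr
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
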