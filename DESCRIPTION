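Package: splicemaps
Title: RNA Splicing Maps, Motif Enrichment, and Co-Regulation Analysis for
    Cassette Exons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for position-dependent analysis of RNA-binding-protein
    motifs around regulated cassette exons. Reads rMATS-dialect differential
    splicing tables, classifies activated/repressed/reference event sets at
    PSI and FDR thresholds, extracts strand-aware exon/intron map segments
    from a genome, scans gapped dimeric (e.g. paired CAC triplets) and IUPAC
    word motifs, builds sliding-window RNA maps with permutation significance,
    detects linked two-motif co-occurrence, performs 8-mer enrichment with
    hierarchical clustering into consensus 5-mers, classifies two-factor
    co-regulation and congruence with a reference tissue splicing programme,
    and runs hypergeometric gene-set overlap tests. Includes a fully seeded
    synthetic-data generator (events, genome, planted motifs, gene sets) so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
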