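Package: barcodeid
Title: Consensus DNA Barcodes from Noisy Long-Read Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs high-accuracy species-identification (DNA barcode)
    consensus sequences from noisy Oxford Nanopore or PacBio amplicon reads.
    Reads are quality-filtered and optionally subsampled, clustered with a
    greedy quality-ordered minimizer scheme, turned into per-cluster draft
    consensus sequences by partial-order alignment (POA), merged across
    reverse-complement duplicates by pairwise alignment identity, polished
    with the cluster's own reads in Racon-style windowed rounds, and
    optionally primer-trimmed with a re-merge and re-polish pass. A seeded
    long-read simulator with a tunable substitution/insertion/deletion error
    model closes the loop so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    withr,
    igraph,
    yaml,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
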