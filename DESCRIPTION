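Package: sketchtax
Title: Containment MinHash Pre-Filtering and Alignment-Based Taxonomic Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-based taxonomic profiling of shotgun metagenomes at desk
    scale. A containment min hash pre-filter sketches each reference genome with
    a bottom-k MinHash over canonical k-mers, estimates the fraction of each
    genome's k-mers present in the read sample (exact set or Bloom filter
    membership, with false-positive correction), and selects a subset database
    of candidate genomes above a containment cutoff, keeping one strain per
    species. Reads aligned against the subset database are filtered by
    aligned-base fraction; uniquely aligned reads establish presence and anchor
    abundances, and multi-aligned reads are redistributed proportionally to
    unique-read evidence. Profiles are aggregated over the NCBI-style rank
    hierarchy and serialized in the CAMI/bioboxes profiling format, with
    precision/recall/F1/L1 evaluation utilities and a synthetic-community
    generator (genomes, strains, error-bearing reads, toy aligner) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    GenomicAlignments
Config/testthat/edition: 3
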