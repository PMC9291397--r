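Package: egtrace
Title: Tracing Endosymbiotic Origins of Organellar Targeting-Peptide Peptidases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for cataloguing the four organellar
    targeting-peptide peptidase families (MPP, SPP, PreP and OOP) across a
    proteome collection and quantifying which bacterial lineages sit closest
    to the eukaryotic homologs. Provides a domain-composition homolog filter
    built on seeded similarity search and phylum-clustered profile scans;
    motif-concatenated gene trees with midpoint rooting, monophyly tests,
    taxon collapsing and misclassification counting; three
    distance-to-closest-eukaryote metrics with top-k and pan-top-k donor
    selection; presence/absence co-occurrence enrichment between
    antimicrobial-peptide-resistant and other bacteria; and sequence-logo
    statistics including a catalytic zinc-binding motif scanner. A
    synthetic gene-family-evolution generator (duplication, loss,
    horizontal and endosymbiotic transfer on a labeled species tree, with
    domain-structured sequences) supplies ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
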