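Package: cernaxis
Title: Competing Endogenous RNA Axis Discovery from Whole-Transcriptome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline that nominates lncRNA/miRNA/mRNA
    competing-endogenous-RNA (ceRNA) axes from two-group whole-transcriptome
    experiments. Implements ensemble coding-potential voting for transcript
    biotype assignment, pooled-count differential expression with
    fold-change/Q-value gates, window-based lncRNA cis-target assignment with
    dual Pearson/Spearman co-expression filters, seed-anchored miRNA
    binding-site scanning with position-weighted complementarity alignment and
    intermolecular duplex minimum-free-energy scoring, and cross-network
    intersection that nominates direction-consistent sponge axes. A seeded
    negative-binomial simulator generates annotation, sequences and count
    matrices with planted ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
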