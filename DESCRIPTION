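Package: fermecol
Title: Community Ecology of Fermented-Grain Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Downstream ecological analysis of solid-state fermentation
    (Baijiu fermented-grain) microbial communities from feature count
    tables: classification of features into six rarity categories
    (always/conditionally abundant, conditionally rare and abundant,
    always/conditionally rare, moderate), alpha diversity and
    rarefaction, Bray-Curtis ordination (PCoA) with PERMANOVA,
    per-stage Spearman co-occurrence networks with modularity-based
    Zi-Pi keystone detection, and phylogenetic null-model inference of
    community assembly processes (beta-nearest taxon index and
    abundance-based Raup-Crick). Includes seeded generators for
    synthetic succession tables, correlated feature blocks, Yule trees
    and communities assembled under known ecological processes, so the
    whole pipeline is testable without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
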