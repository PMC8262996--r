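Package: assemblyproc
Title: Null-Model Inference of Community Assembly Processes for
    Host-Associated Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the ecological processes (homogeneous and variable
    selection, homogeneous dispersal, dispersal limitation, and drift) that
    assemble microbial communities, from an OTU count table, a rooted
    phylogeny, and sample metadata. Implements abundance-weighted beta mean
    nearest taxon distance (betaMNTD) with a tip-shuffling null to obtain the
    beta nearest taxon index (betaNTI), the abundance-based Raup-Crick index
    on Bray-Curtis dissimilarity, five-way process classification of sample
    pairs with aggregation across rarefied replicate tables, group-structured
    process summaries with bootstrap confidence intervals and host- or
    site-induced shifts, core-OTU identification, alpha diversity (Chao1,
    Faith's PD), distance-decay and Mantel statistics, and a synthetic
    community generator that assembles samples under each process with known
    ground truth. Results are tidy tibbles designed for pipe-based workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    phytools,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vegan
Suggests:
    biomformat,
    jsonlite,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
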