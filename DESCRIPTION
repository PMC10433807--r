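Package: dyadtrace
Title: Mother-Infant Microbiome Transfer Events and Strain Identity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects potential vertical "transfer" events of amplicon
    sequence variants (ASVs) within mother-infant dyads at a
    relative-abundance threshold, summarises them per taxon and per dyad,
    and compares groups (Kruskal-Wallis with Dunn's post hoc, chi-square,
    Mann-Whitney U). Complements the amplicon view with genome-level strain
    identity: pairwise SNP distances from whole-genome alignments,
    k-mer-based average nucleotide identity (ANI), gene-content Jaccard
    distances with UPGMA clustering, and within- versus between-dyad
    partitioning of any pairwise matrix. Ships a synthetic-data generator
    for dyad-structured cohorts and genome sets with exact ground truth, so
    the full pipeline is testable without external downloads.
License: MIT
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
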