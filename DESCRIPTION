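Package: mavecall
Title: Simulation and Low-Frequency SNP/MNP Calling for Saturation
    Mutagenesis Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for multiplexed assays of variant effect (MAVE) targeted
    sequencing: a deterministic simulator that edits ultra-low-frequency SNPs
    and MNPs into pre-existing paired-end read sets at specified frequencies
    while prohibiting variant conversion; an end-to-end variant caller with
    mate-concordance filtering, MNP prioritisation (3-nt merge window), primer
    base-quality masking, UMI directional-adjacency consensus deduplication and
    per-mismatch quality-feature extraction; machine-learning error correction
    trained on simulated spike-ins over negative-control libraries; and a
    post-calling filter chain with negative-control background subtraction.
    Includes a synthetic-library generator (amplicon and RACE-like designs,
    UMIs, PCR duplicates, substitution-biased error profiles, NNK codon
    mutagenesis libraries) so every step is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    purrr,
    randomForest,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    Rsamtools,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
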