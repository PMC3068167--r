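Package: crempr
Title: Cysteine-Spacing Module Detection and Repeat Analysis for
    Eggshell Membrane Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and analysing the modular repeat
    architecture of cysteine-rich eggshell membrane proteins (CREMPs)
    and related four-cysteine module proteins. Provides a configurable
    cysteine-spacing grammar (C-X4-C-X5-C-X8-C plus a type-specific
    tail), an anchor-based scanner with weighted-interval chaining, a
    rule-based a/b module classifier driven by diagnostic residues,
    per-position conservation profiles with sequence-logo information
    content, amino-acid composition vectors with Euclidean distances,
    p-distance/UPGMA module segregation statistics, global-alignment
    percent identity, and a seeded synthetic-protein generator with
    ground-truth annotations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
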