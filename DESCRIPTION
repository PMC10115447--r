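Package: bcrcompare
Title: Cross-Species Comparison of Naive B-Cell Receptor Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing naive B-cell receptor (BCR) heavy- and
    light-chain repertoires across species, with presets emulating human,
    C57BL/6 mouse and humanised transgenic (Kymouse) repertoires. Reads and
    writes AIRR Rearrangement tables, profiles germline V/D/J gene usage with
    Z-normalised hierarchical clustering and adjusted-Rand separability under
    repeated subsampling, assigns clonotypes by shared V/J genes and CDRH3
    amino-acid identity, measures Shannon diversity and inter-individual
    sharing, decomposes CDRH3 length differences into five junction-anatomy
    factors by bootstrap estimation, and compares repertoires by usage of
    categorical structural annotations. Includes a seeded V(D)J recombination
    simulator so every analysis is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    igraph,
    jsonlite,
    yaml,
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
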