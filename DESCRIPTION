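Package: fmen
Title: Functional Molecular Ecological Networks from Functional Gene Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline from raw functional-gene-microarray
    spot signals to ecological insight: spot quality control, three-level
    reference-standard normalization, iterative outlier removal, gene
    detection calls and replicate-consistency filtering; intensity-weighted
    diversity indices (richness, Shannon, inverse Simpson); core-gene set
    algebra with Venn partitions; Mantel and partial Mantel permutation tests
    against environmental distance matrices; and random-matrix-theory-based
    co-occurrence network inference, where the similarity threshold is chosen
    by the transition of the nearest-neighbour eigenvalue spacing
    distribution from Wigner-Dyson to Poisson form. Ships a synthetic
    spot-level data generator with known ground truth (treatment effects on
    richness, core-gene membership, block-correlated gene modules) so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
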