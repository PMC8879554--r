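Package: mitonet
Title: Network-Assisted Differential Analysis of Mitochondrial Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for network-assisted systems-biology
    analysis of differential proteomes measured on 2D gels: reference-spot
    (albumin) normalization of spot intensities, bootstrap estimation of
    median-based log2 fold-change effect sizes, construction of
    protein-protein interaction networks from STRING-style edge lists,
    permutation tests of PPI enrichment, Markov clustering (MCL) of the
    differential network, hypergeometric overrepresentation analysis with
    Benjamini-Hochberg FDR, and extension with transcription-factor
    regulatory linksets to screen for regulators whose targets show opposite
    regulation between contrasts. Includes seeded synthetic-data generators
    (spot tables, planted-partition interactomes, annotation sets and
    regulatory linksets with known ground truth) so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
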