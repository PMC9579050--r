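Package: receptoire
Title: Comparative Analysis of Plant Immune-Receptor Gene Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies cell-surface (LRR-RLK, LRR-RLP, LysM-RLK/RLP) and
    intracellular (NB-ARC) immune-receptor families in annotated plant
    proteomes from domain-architecture rules applied to precomputed domain-hit
    and transmembrane tables, assigns LRR-RLK candidates to kinase-domain
    subgroups by local alignment against a reference panel, and quantifies
    concerted expansion and contraction of receptor repertoires across
    species: percentage normalization, Pearson correlation with Bonferroni
    correction, Mantel and partial Mantel permutation tests against a species
    phylogeny, and a resampling test for genomic co-clustering of receptor
    gene groups. Includes a synthetic-data generator that emulates every
    input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
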