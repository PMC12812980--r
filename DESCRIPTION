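Package: trophicnet
Title: Trophic State Assessment and Plankton-Bacteria Co-Occurrence Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for river eutrophication surveys: composite
    Trophic State Index (TSI) scoring and classification from water chemistry
    (chlorophyll-a, total nitrogen, total phosphorus, Secchi depth), community
    diversity metrics (richness, Shannon entropy, seeded rarefaction,
    Bray-Curtis dissimilarity), permutation association tests (Mantel, partial
    Mantel, environment-community correlation), and signed plankton-bacteria
    co-occurrence network construction (tie-aware Spearman correlation with
    Benjamini-Hochberg false-discovery-rate gating) with graph topology metrics
    (Louvain modularity, clustering, path length, cross-kingdom edge
    composition). Includes a synthetic eutrophication-gradient data generator
    that plants known trophic classes, dominance shifts and signed correlation
    blocks so every stage can be validated by recovery of planted truth.
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
    vegan,
    withr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
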