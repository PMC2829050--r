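Package: metamodule
Title: Active Module Discovery in Metabolite Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unbiased pathway modelling of perturbation metabolomics.
    Builds a unipartite metabolite reaction network from compartmented
    reaction tables, converts paired-change Wilcoxon p-values to additive
    node scores through a beta-uniform mixture model with an FDR-derived
    threshold, finds exact maximum-weight connected subgraphs (active
    modules) under randomized imputation of unmeasured nodes, assesses
    their significance by score permutation, and characterizes the
    resulting active module groups with composition-matched hypergeometric
    enrichment, tissue-activity scoring, Spearman correlation clustering
    and principal component analysis. Includes a synthetic-data generator
    with planted ground truth for every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
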