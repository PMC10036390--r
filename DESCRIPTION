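Package: traitnet
Title: Plant Trait Networks from Significance-Thresholded Correlations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds plant trait networks (PTNs) from per-individual trait
    matrices grouped by water body: pairwise Pearson correlations are
    binarized by a significance threshold into an undirected graph whose
    nodes are functional traits.  Provides first-principles node metrics
    (degree, closeness as reciprocal mean shortest path, betweenness) and
    global topology metrics (edge density, average path length, average
    clustering coefficient, Newman modularity with greedy community
    detection), hub and mediator trait identification, coefficient-of-
    variation summaries of trait variability, Pearson screening of
    environmental drivers and backward multiple regression of topology
    metrics on them, and a seeded synthetic-data generator with planted
    correlation modules and environmental gradients so the whole pipeline
    is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
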