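Package: phyllonet
Title: Co-Occurrence Network Analysis of Phyllosphere Mycobiomes and
    Leaf Saponin Accumulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds signed fungal co-occurrence networks from rarefied
    amplicon sequence variant (ASV) tables using Spearman correlation with
    Benjamini-Hochberg masking and a random-matrix-theory (RMT) threshold
    chosen at the Poisson/GOE transition of the eigenvalue nearest-neighbour
    spacing distribution.  Characterises network complexity, efficiency and
    robustness (natural connectivity under random node removal) against
    Erdos-Renyi ensembles, classifies node roles by within-module degree
    z-score and participation coefficient, attributes links to environmental
    filtering, dispersal limitation or residual biotic interaction, screens
    network modules against leaf saponin profiles with paired random-forest
    and k-nearest-neighbour cross-validation, identifies positive regulation
    modules and taxa via stochasticity-ratio null models and observed-variable
    path analysis, and tests order-level enrichment of positive regulation
    taxa.  Includes a seeded synthetic-community generator with planted
    module, environmental, dispersal and saponin structure for end-to-end
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    caret,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
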