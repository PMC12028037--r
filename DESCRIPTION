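Package: mycostab
Title: Complexity and Stability of Microbial Co-Occurrence Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of microbial community complexity and
    stability from amplicon feature tables, motivated by soil fungal
    communities in mangrove ecosystems. Provides alpha/beta diversity
    statistics (Shannon index, Bray-Curtis distances, principal coordinates
    analysis, ANOSIM and Mantel permutation tests with exhaustive-enumeration
    oracles), signed Spearman co-occurrence networks with Louvain module
    detection and module-hub identification, per-sample cohesion
    (abundance-weighted connectedness) as a complexity index, network
    robustness under random or targeted node removal with secondary
    extinctions as a stability index, environmental driver screening via
    Spearman correlation tables and simple regressions, a partial least
    squares path modeling (PLS-PM) engine with bootstrap inference, and a
    seeded synthetic community generator with known ground truth for
    validating every stage. A configuration-driven pipeline orchestrates all
    stages reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
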