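Package: bops
Title: Small Protein Complex Prediction by Balanced-Weight PPI Network
    Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts small protein complexes (up to ten subunits) from
    weighted protein-protein interaction networks. Edge weights are first
    rebalanced to emphasise core-attachment structure, the network is then
    split recursively by minimum-bottleneck cuts into pieces of bounded
    size, and all connected subsets of each piece are enumerated, scored by
    a cohesion statistic, deduplicated by neighbourhood-affinity similarity
    and ranked. Ships the standard evaluation metric suite for complex
    prediction (precision/recall/F-score, Sn/PPV/ACC, maximum matching
    ratio, expected regression ratio of a segmentation, hypergeometric
    enrichment p-values) together with a reproducible synthetic network
    generator with planted complexes for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
LinkingTo:
    Rcpp
RoxygenNote: 7.3.3
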