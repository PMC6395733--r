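Package: bgcmodules
Title: Detection and Prioritisation of Co-Evolving Gene Modules in
    Biosynthetic Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Unsupervised detection of putative biosynthetic subclusters
    (modules) in collections of gene clusters. Orthogroup (smCOG) pairs are
    tested for statistically surprising adjacency and colocalization using
    exact multivariate hypergeometric tail probabilities, the resulting
    p-values are corrected with the Benjamini-Yekutieli procedure, and
    modules are enumerated as maximal cliques of the significance network
    over a ladder of thresholds. Detected modules are ranked with a
    weighted-rank interest score combining size, compound-class Shannon
    entropy, cluster support, significance, and functional-category
    composition. Includes readers for cluster tables and GenBank feature
    tables, a synthetic benchmark generator with planted modules, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
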