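Package: nbrclust
Title: Node-Based Resilience Clustering of Point Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Clusters numeric feature tables by converting them to k-nearest-
    neighbour graphs at minimal connectivity and finding critical attack sets
    of nodes whose removal disconnects the graph.  Three node-based resilience
    measures (vertex attack tolerance, normalized integrity, tenacity) are
    minimized with a greedy weighted-betweenness heuristic; the surviving
    components become clusters, optionally after folding the attack set back
    in, and are merged or split to a requested cluster count.  Candidate
    configurations are scored with nine internal cluster validation indices
    plus graph modularity and conductance, and ranked by majority vote.
    Includes preprocessing (imputation, range normalization, correlation
    filtering) and seeded synthetic-data generators for benchmarking.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    mclust,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
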