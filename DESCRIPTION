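Package: tempoph
Title: Topology-Assisted Temporal Clustering of Dynamic Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Temporal clustering of dynamic functional connectivity networks
    (dFCN) using 0-dimensional persistent homology. Per-timepoint brain
    networks are summarized as H0 persistence diagrams of a Vietoris-Rips
    filtration, compared through exact Wasserstein distances, embedded with
    metric multidimensional scaling and clustered by silhouette-selected
    k-means, so that the number of recovered temporal brain states can be
    compared across acquisition protocols with different sampling periods
    (TR). Includes three non-topological baseline pipelines (direct
    clustering of flattened networks, PCA-reduced clustering, and
    Euclidean-distance dFCN clustering), cross-cohort cluster-count
    consistency statistics, and a synthetic multi-rate dFCN generator with
    planted discrete connectivity states for ground-truthed evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
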