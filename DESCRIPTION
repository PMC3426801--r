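Package: scgclust
Title: Self-Consistency Grouping: Stringent Rank-Based Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Self-consistency grouping (SCG) is a stringent clustering
    method in which a set of k objects is a cluster only if every pairwise
    similarity rank within the set is at most k. The package builds
    asymmetric rank matrices from distance or similarity data (dense
    matrices or sparse pairwise score lists), implements three SCG
    algorithms (a direct enumeration over cluster sizes, a fast variant
    guaranteed to find all independent clusters, and a candidate-index
    scheduler that recovers the complete subcluster structure), manages
    the resulting laminar cluster forest with Newick export, provides
    single/complete/average linkage baselines and an iterative SCG
    extension, evaluates clusterings against a reference partition by
    pair counting, and reproduces a noise-robustness simulation in which
    pairwise distances of planar Gaussian blobs are perturbed with
    Gaussian errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    mclust,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
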