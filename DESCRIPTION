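Package: gsclust
Title: Clustering and Integration of Gene-Set Analysis Results
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Harmonizes gene-set analysis (GSA) results from multiple tools
    and experiments into a single collection, computes pairwise gene-set
    similarity (relative risk, Jaccard index, Cohen's kappa, or a custom
    metric), clusters gene-sets into groups of shared gene content with
    data-driven selection of the number of clusters (elbow, gap statistic,
    silhouette), and exports cluster summaries, highlight scores, heatmaps,
    dendrograms, and thresholded similarity networks. Readers are provided
    for GMT files, Ingenuity Pathway Analysis (IPA) canonical-pathway
    exports, GREAT region-enrichment exports, and generic name-plus-gene-list
    tables. A local hypergeometric over-representation analysis annotates
    clusters against a user-supplied GMT. Deterministic synthetic fixture
    generators with planted cluster structure support fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    grid,
    cluster,
    pheatmap,
    igraph,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
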