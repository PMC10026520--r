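Package: ccrecluster
Title: Index-Set Clustering of Candidate Cis-Regulatory Elements Across Cell Types
Version: 0.1.0
Authors@R:
    person("ccrecluster", "authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Clusters candidate cis-regulatory elements (cCREs) across an
    ordered series of cell types using a binarized presence/absence index.
    cCREs sharing an index form an Index-Set (IS); a negative-binomial
    background on IS sizes separates abundant ISs from sparse ones, a
    quadratic discriminant model rescues cCREs from sparse ISs back into
    abundant ones (or a null class), and abundant ISs are merged into
    Meta-ISs by hierarchical clustering with an AIC-selected cut. The
    package also assigns dominant epigenetic states to cCREs from a
    genome segmentation, provides signal normalization (scaling, quantile,
    signal-to-noise anchoring), interpretability (sliding-window Shannon
    entropy) and reproducibility (noise-injection adjusted Rand index)
    diagnostics, visualization of cluster maps and per-cluster panels, a
    synthetic-fixture generator with ground truth, and an end-to-end
    pipeline driver with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    limma,
    jsonlite,
    optparse,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
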