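Package: cortid
Title: Hierarchical Cell-Identity Classification and Diversity Analysis for
    Cortical Single-Cell Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a three-level (class/subclass/type) reference taxonomy of
    cortical cell populations from single-cell or single-nucleus RNA-seq
    counts, selects identity-defining marker genes per hierarchical level,
    and classifies query cells by a 10-nearest-neighbour consensus rule in an
    identity embedding with an explicit undefined outcome. Also quantifies
    cellular diversity via the Shannon index of cluster composition, stages
    cells on a maturation axis with a regularized ordinal-regression
    pseudo-age model, and partitions condition-dependent differentially
    expressed genes into restored versus in-vivo-only sets. Ships a seeded
    negative-binomial simulator of nested cell-population structure,
    maturation ramps, and culture-condition effects so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    igraph,
    RANN,
    uwot,
    vegan,
    matrixStats,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    withr,
    jsonlite
Config/testthat/edition: 3
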