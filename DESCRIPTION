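Package: scgraphsurv
Title: Survival Modelling on Sample-Specific Gene Graphs from Single-Cell
    and Bulk Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates single-cell and bulk RNA-seq expression into
    per-patient gene graphs and trains a graph attention network with
    MinCut pooling and a Transformer encoder under a regularized Cox
    partial-likelihood loss. Provides univariate Cox screening of
    prognostic genes, cell-to-sample rank-correlation scoring for
    per-sample key-gene selection, k-nearest-neighbour gene-graph
    construction with cross-modality fusion, risk scoring with
    maximally selected rank-statistic cutpoints, Kaplan-Meier and
    log-rank survival statistics, Harrell's concordance index, and
    attention-based node, edge and module interpretability, together
    with a simulator of paired single-cell/bulk cohorts with planted
    prognostic structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
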