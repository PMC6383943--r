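Package: microrepop
Title: Spatial, Turnover, and Transcriptome Kinetics of Microglial Repopulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of microglial recolonization after
    pharmacological ablation. Provides spatial point-pattern statistics for
    segmented cell centroids (nearest-neighbor distances, Ripley's K- and
    H-functions with edge correction, moving-average smoothing, and cluster
    domain-size estimation), kernel-density cluster-boundary extraction with
    dual-color overlap quantification, one-phase exponential decay fitting of
    EdU pulse-chase cell densities with half-life estimation, and count-based
    transcriptome kinetics (CPM filtering, TMM normalization, per-timepoint
    differential expression, fast/medium/slow/delayed return-class
    assignment, Poisson-distance similarity, and k-means expression
    clustering). A synthetic-data module generates clustered clonal point
    patterns, decay series, and negative-binomial count matrices with planted
    ground truth so every stage can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    edgeR,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
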