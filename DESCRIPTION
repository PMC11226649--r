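Package: tamtools
Title: Signature Scoring and Composition Analysis for Tumour-Associated Macrophage Atlases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis toolkit for pan-cancer single-cell atlases of
    tumour-associated macrophages (TAMs). Provides rank-based (UCell-style) and
    control-bin module scoring of gene signatures per cell, one-vs-rest marker
    derivation and top-10 cluster signatures, a standard-deviation rule for
    selecting macrophage clusters, signature-specificity metrics with a
    gold-standard gate, differential cluster-composition testing on
    arcsin-square-root transformed proportions with empirical-Bayes variance
    moderation, covariate-adjusted gene ranking with preranked gene-set
    enrichment analysis, quartile-stratified rank tests, cluster co-occurrence
    with principal-coordinates ordination, spatial subset assignment by score
    thresholds with k-nearest-neighbour composition, and marker-percentile
    membership profiling. Includes negative-binomial single-cell, bulk-cohort
    and spatial point-pattern simulators with known ground truth so that every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    fgsea,
    jsonlite,
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
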