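Package: stabilityDE
Title: Resampling-Stability Differential Expression with Permutation
    Nulls, Pre-Ranked GSEA and Regional Gene-Set Construction
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Differential-expression analysis for small, heterogeneous
    cohorts based on resampling stability: moderated t-tests are run over
    many gender-balanced subgroups of samples, a class-label-permutation
    null is built the same way, and each transcript's observed p-value
    distribution is compared against its permutation null with a
    Kruskal-Wallis test converted to Storey q-values. Transcripts are
    ranked by detection recurrence and summed log2 fold change. The summed
    fold-change ranking feeds a pre-ranked gene set enrichment analysis
    with a gene-label permutation null, and a consensus builder derives
    brain-region gene sets from multi-donor regional expression by
    per-donor pairwise contrasts. A synthetic-data generator with known
    ground truth supports calibration and recovery benchmarking of the
    whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
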