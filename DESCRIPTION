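Package: scTypeBench
Title: Benchmarking Cell-Type Annotation Methods for scRNA-Seq Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for assigning cell-type labels to single-cell
    RNA-seq cell clusters and benchmarking the methods that do so. Five
    scoring methods operate on a cluster-average expression matrix and
    cell-type signatures: over-representation analysis (ORA), preranked
    gene-set enrichment analysis (GSEA), gene-set variation analysis
    (GSVA)-style scoring, nu-support-vector-regression deconvolution
    (CIBERSORT-style), and directional neighbor voting
    (MetaNeighbor-style). Includes ROC and precision-recall evaluation
    against gold-standard cluster annotations, signature-subsampling
    robustness simulations, a synthetic-data generator with planted
    marker structure, and readers and writers for GMT gene sets,
    expression tables, and gold-standard maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    fgsea,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
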