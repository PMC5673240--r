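Package: transephys
Title: Relating Cell-Type-Specific Gene Expression to Neuronal Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and validating associations between
    cell-type-specific transcriptomes and intrinsic electrophysiological
    properties of neurons. Implements cross-study normalization of curated
    electrophysiology measurements with penalized spline-covariate
    regression, expression preprocessing (quantile normalization, probe
    collapse, mean/variance gene filtering, single-cell aggregation),
    harmonization of expression and electrophysiology cell types, a
    per-gene Spearman correlation screen with Benjamini-Hochberg false
    discovery rate control, permutation-calibrated cross-dataset
    consistency statistics, and sparse two-stage elastic-net models that
    predict electrophysiological values from multivariate expression,
    including transfer to an independently normalized single-cell dataset.
    A synthetic-data generator with planted gene-phenotype effects and
    study-level nuisance effects provides ground truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    limma,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
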