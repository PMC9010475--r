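Package: cortexperm
Title: Cluster-Based Permutation Inference for Longitudinal Change in
    Parcellated Cortical Measures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting group differences in longitudinal change of
    parcellated cortical measures such as the T1w/T2w ratio. Computes the
    symmetrised percentage change between two timepoints, fits region-wise
    linear models with nuisance covariates, and controls the family-wise error
    rate with a permutation-based maximum-cluster-size correction on a
    region-adjacency graph. Includes Hedges g effect sizes, cluster-level
    sensitivity analyses (covariate adjustment, outlier exclusion, cortical
    depth), change-by-group interaction models with FDR correction, and a
    synthetic cohort generator with planted contiguous effects for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
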