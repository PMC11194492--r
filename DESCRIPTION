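Package: spatiomol
Title: Whole-Brain Spatiomolecular Gradient Analysis by Partial Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers directional gradients of gene expression across the brain by
    cross-decomposing a sample-by-gene expression matrix with the samples' 3D
    stereotaxic coordinates using partial least squares (PLS) regression.
    Provides out-of-sample coordinate prediction and per-axis R2, repeated
    cross-validated component selection, spatial-permutation stability tests,
    projection of fitted gradients into external regional datasets with
    permutation-based regional similarity, developmental trajectories of
    gradient consolidation, cortical surface interpolation, molecular-territory
    clustering with spin-test nulls and partition comparison (ARI/AMI),
    bootstrapped variance-explained model comparison, and tail-based selection
    and permutation overlap testing of gradient-associated genes. Includes a
    synthetic-data generator that plants known orthonormal spatial gradients so
    every stage of the pipeline can be exercised against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    cluster,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
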