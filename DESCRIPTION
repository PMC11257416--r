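Package: censoredCP
Title: Censored Least Squares CP Tensor Factorization with Missing Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Canonical polyadic (PARAFAC) decomposition of dense N-mode
    tensors that contain missing values. Provides three solvers: censored
    alternating least squares, which solves each row of a factor matrix by
    least squares restricted to that row's observed columns with rows grouped
    by shared missingness pattern; alternating least squares with single
    imputation, which refills missing entries from the current reconstruction
    before every sweep; and gradient-based direct optimization of the masked
    reconstruction loss. Includes entrywise and chordwise held-out masking for
    imputation-based cross-validation, the fitting/imputation error split,
    multi-replicate multi-rank benchmarking with median and interquartile
    summaries and best-imputed-rank selection, a synthetic low-rank tensor
    generator with controlled noise and missingness, and plain-text tensor
    input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Software, DimensionReduction, StatisticalMethod
RoxygenNote: 7.3.3
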