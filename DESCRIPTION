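Package: sspca
Title: Super-Sparse Principal Component Analysis via Random-Effect
    Penalties and Condition-Number Shrinkage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sparse principal component analysis for high-dimensional
    genomic data.  Loadings are estimated with a modified NIPALS
    (nonlinear iterative partial least squares) algorithm in which the
    regression step is penalized through a gamma random-effect
    (h-likelihood) model.  The resulting penalty family interpolates
    between ridge (w = 0), a LASSO-like cusp (w = 2) and penalties
    unbounded at the origin (w > 2) that drive most loadings exactly to
    zero.  A condition-number constraint on the sample covariance
    spectrum shrinks the singular values of the data matrix before
    loading estimation ("super-sparse" PCA).  Includes moment/CV tuning
    of the penalty parameters, a row-wise permutation test for the
    number of significant components, adjusted-variance reporting for
    correlated sparse scores, a single-factor simulation engine for
    benchmarking, and delimited-text I/O with a small command-line
    driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
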