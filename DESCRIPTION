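Package: partGLS
Title: Partitioned Generalized Least Squares Tests for Large Autocorrelated Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hypothesis tests (F, likelihood-ratio, t) for large spatially
    autocorrelated datasets by generalized least squares on random partitions.
    The dataset is split into non-overlapping random partitions, each partition
    is analyzed by exact GLS, the analytic correlations among the partitions'
    test statistics are computed from the cross-partition error correlation,
    and the per-partition statistics are combined into calibrated overall
    tests via the distribution of quadratic forms in Gaussian variables.
    Includes a spatiotemporal front-end that fits per-pixel time-series trend
    models (least squares or AR(1) errors by REML), estimates the spatial
    correlation range from time-series residuals, and analyzes the spatial
    field of trend estimates, plus simulation generators and validation
    harnesses for type-I error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr
Config/testthat/edition: 3
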