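Package: longswe
Title: Sandwich-Estimator Marginal Models for Longitudinal and Repeated-Measures Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-iterative marginal modelling of longitudinal and
    repeated-measures data, mass-univariate or univariate. Coefficients are
    estimated by ordinary least squares and their covariance by the
    cluster-robust sandwich estimator, in a heterogeneous (per-subject) or
    homogeneous (per-group common covariance) form, with HC1/HC2/HC3-type
    small-sample residual adjustments. Wald inference uses effective degrees
    of freedom obtained by moment matching. Includes a missing-data-aware
    Box test of compound symmetry, naive-OLS and summary-statistics OLS
    baselines, a Monte-Carlo harness for false-positive-rate and power
    studies, synthetic design and covariance generators, NIfTI voxelwise
    execution, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    jsonlite,
    withr,
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
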