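#' Ordinary least squares fit for one or many responses
#'
#' Fits the marginal model y = X beta + e columnwise by OLS (working
#' independence). This is the point-estimation half of the sandwich-estimator
#' method: coefficients come from plain OLS and all covariance modelling is
#' deferred to the robust covariance step.
#'
#' @param design an `swe_design`.
#' @param Y numeric vector (one response) or n x V matrix (V responses,
#'   e.g. voxels), rows matching the design rows.
#' @return list with `beta` (p x V) and `residuals` (n x V).
#' @export
fit_ols <- function(design, Y) {
  stopifnot(inherits(design, "swe_design"))
  Y <- .as_response(design, Y)
  beta <- design$XtX_inv %*% crossprod(design$X, Y)
  res <- Y - design$X %*% beta
  rownames(beta) <- colnames(design$X)
  list(beta = beta, residuals = res)
}
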