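#' Naive-OLS baseline (subject-dummy model)
#'
#' Classical longitudinal baseline: an OLS model with one indicator column
#' per subject absorbing between-subject variation, plus the within-subject
#' columns of the supplied design, tested with the classical F (df = n minus
#' the parameter count). Pure between-subject effects are linear
#' combinations of the subject dummies and therefore cannot be tested; such
#' contrasts are rejected with an error. The test is exact only under
#' compound symmetry in a balanced design.
#'
#' @param design an `swe_design` (its within-subject columns are reused).
#' @param Y response vector or n x V matrix.
#' @param contrast contrast over the original design columns; all nonzero
#'   weights must fall on within-subject columns.
#' @return data frame (class `swe_test`) with `stat`, `df1`, `df2`, `p` per
#'   response; also columns `beta` when q = 1.
#' @export
n_ols_fit <- function(design, Y, contrast) {
  stopifnot(inherits(design, "swe_design"))
  Y <- .as_response(design, Y)
  C <- .as_contrast(contrast, design$p)
  btw <- .between_columns(design)
  if (any(abs(C[, btw, drop = FALSE]) > 0))
    stop("contrast not estimable under N-OLS: it involves between-subject ",
         "columns, which are linear combinations of the subject dummies")
  within_cols <- which(!btw)
  dummies <- matrix(0, design$n, design$m)
  for (i in seq_along(design$subjects))
    dummies[design$subj_rows[[design$subjects[i]]], i] <- 1
  Xn <- cbind(dummies, design$X[, within_cols, drop = FALSE])
  pN <- ncol(Xn)
  if (qr(Xn)$rank < pN) stop("N-OLS design is rank deficient")
  Cn <- cbind(matrix(0, nrow(C), design$m), C[, within_cols, drop = FALSE])
  .classical_f(Xn, Y, Cn, df2 = design$n - pN)
}

## classical OLS F-test of C beta = 0, vectorised over responses
.classical_f <- function(X, Y, C, df2) {
  if (df2 <= 0) stop("no residual degrees of freedom for the classical F-test")
  XtXi <- chol2inv(chol(crossprod(X)))
  beta <- XtXi %*% crossprod(X, Y)
  res <- Y - X %*% beta
  s2 <- colSums(res * res) / df2
  cb <- C %*% beta
  M <- C %*% XtXi %*% t(C)
  q <- nrow(C)
  Mi <- solve(M)
  if (q == 1L) {
    Fstat <- as.numeric(cb)^2 * as.numeric(Mi) / s2
  } else {
    Fstat <- colSums(cb * (Mi %*% cb)) / s2
  }
  Fstat <- Fstat / q
  out <- data.frame(stat = Fstat, df1 = q, df2 = df2,
                    p = stats::pf(Fstat, q, df2, lower.tail = FALSE))
  if (q == 1L) out$beta <- as.numeric(cb)
  class(out) <- c("swe_test", class(out))
  out
}

#' Summary-statistics OLS baseline
#'
#' Two-stage baseline: (1) each subject's responses are regressed on the
#' subject's own rows of the design (restricted to the columns it actually
#' uses) and a scalar summary w' beta_i is extracted; (2) the one-value-per-
#' subject summaries are regressed on group indicators and a classical
#' F-test is applied to a contrast over group means. Subjects whose stage-1
#' model is not estimable are dropped with a warning.
#'
#' @param design an `swe_design`.
#' @param Y response vector or n x V matrix.
#' @param within length-p weight vector defining the per-subject summary in
#'   design-column coordinates (weights on columns a subject does not use
#'   are ignored for that subject).
#' @param group_contrast contrast over group means, in `design$groups`
#'   order; defaults to all-pairwise-differences against the first group.
#' @return list with `test` (data frame, class `swe_test`), `summaries`
#'   (m_used x V matrix), `subjects_used` and `n_dropped`.
#' @export
ss_ols_fit <- function(design, Y, within, group_contrast = NULL) {
  stopifnot(inherits(design, "swe_design"))
  Y <- .as_response(design, Y)
  within <- as.numeric(within)
  if (length(within) != design$p)
    stop("within must have length p = ", design$p)
  m <- design$m
  V <- ncol(Y)
  summ <- matrix(NA_real_, m, V)
  ok <- logical(m)
  ## columns in scope for each group (nonzero somewhere in the group's rows)
  scope <- lapply(design$groups, function(g)
    which(colSums(design$X[design$group == g, , drop = FALSE] != 0) > 0))
  names(scope) <- design$groups
  for (i in seq_len(m)) {
    r <- design$subj_rows[[design$subjects[i]]]
    Xi <- design$X[r, , drop = FALSE]
    use <- which(colSums(Xi != 0) > 0)
    ## a weighted column that exists in the subject's group but is
    ## degenerate for this subject makes the summary inestimable
    missing_req <- setdiff(intersect(scope[[design$subj_group[[i]]]],
                                     which(within != 0)), use)
    if (length(missing_req)) next
    Xi <- Xi[, use, drop = FALSE]
    ## within a subject some design columns coincide (e.g. an intercept and
    ## a between-subject covariate); keep a maximal independent subset
    qri <- qr(Xi)
    keep <- qri$pivot[seq_len(qri$rank)]
    if (any(within[use[-keep]] != 0)) next     # summary not estimable
    if (!length(keep) || nrow(Xi) < length(keep)) next
    Xi <- Xi[, keep, drop = FALSE]
    bi <- qr.solve(Xi, Y[r, , drop = FALSE])
    summ[i, ] <- crossprod(within[use[keep]], bi)
    ok[i] <- TRUE
  }
  if (!all(ok))
    warning(sum(!ok), " subject(s) dropped: stage-1 summary not estimable")
  if (!any(ok)) stop("no subject has an estimable stage-1 summary")
  summ <- summ[ok, , drop = FALSE]
  grp <- design$subj_group[ok]
  groups <- design$groups
  G <- matrix(0, sum(ok), length(groups))
  G[cbind(seq_len(sum(ok)), match(grp, groups))] <- 1
  if (is.null(group_contrast)) {
    if (length(groups) < 2) stop("group_contrast needed for a single group")
    group_contrast <- cbind(-1, diag(length(groups) - 1))
  }
  Cg <- if (is.vector(group_contrast)) matrix(group_contrast, 1) else
    as.matrix(group_contrast)
  if (ncol(Cg) != length(groups))
    stop("group_contrast must have one column per group")
  present <- colSums(G) > 0
  if (!all(present)) {
    if (any(abs(Cg[, !present, drop = FALSE]) > 0))
      stop("group_contrast involves a group with no usable subjects")
    G <- G[, present, drop = FALSE]
    Cg <- Cg[, present, drop = FALSE]
  }
  test <- .classical_f(G, summ, Cg, df2 = nrow(G) - ncol(G))
  list(test = test, summaries = summ,
       subjects_used = design$subjects[ok], n_dropped = sum(!ok))
}
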