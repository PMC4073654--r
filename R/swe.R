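#' Small-sample residual adjustments
#'
#' Rescales OLS residuals before they enter the robust covariance estimator.
#' `S0` leaves them untouched (HC0), `S1` applies the global factor
#' sqrt(n/(n-p)) (HC1), `S2` divides each row by sqrt(1 - h) (HC2) and `S3`
#' by (1 - h) (HC3), where h is the hat-matrix diagonal. The leverage-based
#' adjustments correct the downward bias of residual cross-products in small
#' samples.
#'
#' @param residuals n x V matrix of raw OLS residuals.
#' @param h length-n hat diagonals from the same design.
#' @param n,p observation and parameter counts of that design.
#' @param adjustment one of "S0", "S1", "S2", "S3".
#' @return adjusted residual matrix, same shape.
#' @export
adjust_residuals <- function(residuals, h, n, p,
                             adjustment = c("S0", "S1", "S2", "S3")) {
  adjustment <- match.arg(adjustment)
  residuals <- as.matrix(residuals)
  f <- .adjust_factors(h, n, p, adjustment)
  if (is.null(f)) residuals else residuals * f
}

## per-row multiplicative factors; NULL means identity
.adjust_factors <- function(h, n, p, adjustment) {
  switch(adjustment,
    S0 = NULL,
    S1 = rep(sqrt(n / (n - p)), length(h)),
    S2 = , S3 = {
      sat <- which(h >= 1 - 1e-12)
      if (length(sat))
        stop(adjustment, " adjustment undefined: leverage 1 at row(s) ",
             paste(sat, collapse = ", "))
      if (adjustment == "S2") 1 / sqrt(1 - h) else 1 / (1 - h)
    })
}

#' Heterogeneous (per-subject) sandwich covariance
#'
#' Classic cluster-robust covariance of the OLS coefficients: each subject's
#' covariance is estimated by the outer product of its own (adjusted)
#' residual vector, giving
#' S = (X'X)^-1 [ sum_i X_i' e_i e_i' X_i ] (X'X)^-1.
#'
#' @param design an `swe_design`.
#' @param residuals_adjusted n x V adjusted residuals from [fit_ols()] /
#'   [adjust_residuals()] on the same design.
#' @return p x p x V array of covariance matrices.
#' @export
swe_heterogeneous <- function(design, residuals_adjusted) {
  E <- .as_response(design, residuals_adjusted)
  S_flat <- .swe_het_flat(design, E)
  .flat_to_array(S_flat, design$p)
}

.swe_het_flat <- function(design, E) {
  p <- design$p
  V <- ncol(E)
  meat <- matrix(0, p * p, V)
  i1 <- rep(seq_len(p), times = p)
  i2 <- rep(seq_len(p), each = p)
  for (r in design$subj_rows) {
    Gi <- crossprod(design$X[r, , drop = FALSE], E[r, , drop = FALSE])
    meat <- meat + Gi[i1, , drop = FALSE] * Gi[i2, , drop = FALSE]
  }
  (design$XtX_inv %x% design$XtX_inv) %*% meat
}

.flat_to_array <- function(S_flat, p) {
  V <- ncol(S_flat)
  array(S_flat, dim = c(p, p, V))
}

#' Per-group common covariance estimate
#'
#' Estimates, for each group, a single covariance matrix over visit
#' categories that is shared by all the group's subjects. Diagonal entries
#' are mean squared residuals over the subjects observed at that visit
#' (1/m normalisation, deliberately without the usual m-1 correction, since
#' small-sample bias is handled by the residual adjustments); off-diagonal
#' entries combine the correlation estimated from the subjects observed at
#' both visits with the marginal standard deviations. Because under missing
#' data different entries are estimated from different subject subsets, the
#' assembled matrix can fail to be positive semi-definite; a spectral repair
#' (negative eigenvalues clamped to zero) is always applied and flagged.
#'
#' @param design an `swe_design`.
#' @param residuals_adjusted n x V adjusted residuals.
#' @return an object of class `swe_group_cov`: per group, the visit labels,
#'   the pair-count matrix `M` (diagonal = per-visit subject counts), the
#'   covariance array `V` (k x k x V responses), the correlation array `rho`,
#'   and a per-response `repaired` flag.
#' @export
estimate_group_covariance <- function(design, residuals_adjusted) {
  E <- .as_response(design, residuals_adjusted)
  V <- ncol(E)
  out <- list()
  for (g in design$groups) {
    lev <- design$visit_levels[[g]]
    K <- length(lev)
    rowmap <- .group_rowmap(design, g)     # K x m_g, 0 = missing
    m_g <- ncol(rowmap)
    M <- matrix(0L, K, K, dimnames = list(lev, lev))
    Vg <- array(0, dim = c(K, K, V))
    Rg <- array(0, dim = c(K, K, V))
    dg <- matrix(0, K, V)                  # diagonal variances
    for (k in seq_len(K)) {
      rk <- rowmap[k, ]
      obs <- rk > 0L
      M[k, k] <- sum(obs)
      if (M[k, k] == 0L)
        stop("visit category '", lev[k], "' in group '", g,
             "' has no observations")
      Ek <- E[rk[obs], , drop = FALSE]
      dg[k, ] <- colSums(Ek * Ek) / M[k, k]
      Vg[k, k, ] <- dg[k, ]
      Rg[k, k, ] <- 1
    }
    zero_pairs <- character(0)
    if (K > 1) {
      for (k in seq_len(K - 1)) for (kp in (k + 1):K) {
        both <- rowmap[k, ] > 0L & rowmap[kp, ] > 0L
        M[k, kp] <- M[kp, k] <- sum(both)
        if (M[k, kp] == 0L) {
          zero_pairs <- c(zero_pairs, paste0(lev[k], "/", lev[kp]))
          next                             # rho = 0, covariance 0
        }
        Ea <- E[rowmap[k, both], , drop = FALSE]
        Eb <- E[rowmap[kp, both], , drop = FALSE]
        sab <- colSums(Ea * Eb)
        den <- sqrt(colSums(Ea * Ea) * colSums(Eb * Eb))
        rho <- ifelse(den > 0, sab / den, 0)
        Rg[k, kp, ] <- Rg[kp, k, ] <- rho
        cv <- rho * sqrt(dg[k, ] * dg[kp, ])
        Vg[k, kp, ] <- Vg[kp, k, ] <- cv
      }
    }
    if (length(zero_pairs))
      warning("group '", g, "': no subject observed at both visits ",
              paste(zero_pairs, collapse = ", "),
              "; corresponding covariance set to 0")
    ## always-on spectral PSD repair (idempotent when already PSD)
    repaired <- logical(V)
    for (v in seq_len(V)) {
      rep_v <- psd_repair(Vg[, , v])
      if (!identical(attr(rep_v, "repaired"), FALSE)) {
        Vg[, , v] <- rep_v
        repaired[v] <- TRUE
      }
    }
    out[[g]] <- list(group = g, visits = lev, M = M, V = Vg, rho = Rg,
                     m = m_g, repaired = repaired,
                     zero_pairs = zero_pairs)
  }
  structure(list(groups = design$groups, est = out, V = V),
            class = "swe_group_cov")
}

## K x m_g matrix mapping (visit index, subject) -> design row (0 = missing)
.group_rowmap <- function(design, g) {
  subj <- design$subjects[design$subj_group == g]
  K <- length(design$visit_levels[[g]])
  rowmap <- matrix(0L, K, length(subj))
  colnames(rowmap) <- subj
  for (j in seq_along(subj)) {
    r <- design$subj_rows[[subj[j]]]
    rowmap[design$visit_idx[r], j] <- r
  }
  rowmap
}

#' Spectral positive semi-definite repair
#'
#' Eigendecomposes a symmetric matrix, clamps negative eigenvalues to zero
#' and reconstructs. Matrices that are already PSD (up to a relative
#' tolerance of 1e-12) are returned unchanged, which makes the operation
#' idempotent.
#'
#' @param V symmetric numeric matrix.
#' @return PSD matrix; attribute `repaired` says whether anything changed.
#' @export
psd_repair <- function(V) {
  V <- as.matrix(V)
  if (nrow(V) != ncol(V) ||
      max(abs(V - t(V))) > 1e-8 * max(1, max(abs(V))))
    stop("psd_repair needs a symmetric matrix")
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE)
  tol <- 1e-12 * max(abs(ev$values), 0)
  if (all(ev$values >= -tol)) {
    attr(V, "repaired") <- FALSE
    return(V)
  }
  lam <- pmax(ev$values, 0)
  out <- ev$vectors %*% (lam * t(ev$vectors))
  out <- (out + t(out)) / 2
  attr(out, "repaired") <- TRUE
  out
}

#' Homogeneous (per-group) sandwich covariance
#'
#' Assembles the sandwich covariance using, for every subject, the rows and
#' columns of its group's common covariance estimate indexed by the
#' subject's observed visits. When every subject is its own group this
#' reduces exactly to the heterogeneous estimator.
#'
#' @param design an `swe_design`.
#' @param group_cov an `swe_group_cov` from [estimate_group_covariance()].
#' @return p x p x V array of covariance matrices.
#' @export
swe_homogeneous <- function(design, group_cov) {
  stopifnot(inherits(group_cov, "swe_group_cov"))
  S_flat <- .swe_hom_flat(design, group_cov)
  .flat_to_array(S_flat, design$p)
}

.swe_hom_flat <- function(design, group_cov) {
  p <- design$p
  V <- group_cov$V
  meat <- matrix(0, p * p, V)
  for (g in design$groups) {
    gc <- group_cov$est[[g]]
    K <- length(gc$visits)
    rowmap <- .group_rowmap(design, g)
    ## voxel-independent pair aggregates P_kk' = sum_i x_ik x_ik''
    PP <- matrix(0, p * p, K * K)
    for (k in seq_len(K)) for (kp in seq_len(K)) {
      both <- rowmap[k, ] > 0L & rowmap[kp, ] > 0L
      if (!any(both)) next
      Xa <- design$X[rowmap[k, both], , drop = FALSE]
      Xb <- design$X[rowmap[kp, both], , drop = FALSE]
      PP[, (kp - 1L) * K + k] <- as.vector(crossprod(Xa, Xb))
    }
    meat <- meat + PP %*% matrix(gc$V, K * K, V)
  }
  (design$XtX_inv %x% design$XtX_inv) %*% meat
}

#' Fit the full sandwich-estimator model
#'
#' One-stop fit: OLS coefficients, residual adjustment, robust covariance in
#' the requested variant, and (for the homogeneous variant) the per-group
#' common covariance estimate. The default `S3` adjustment with the
#' homogeneous variant is the recommended configuration for longitudinal
#' designs with groups of exchangeable subjects.
#'
#' @param design an `swe_design`.
#' @param Y response vector or n x V matrix.
#' @param variant "hom" (per-group common covariance, default) or "het"
#'   (per-subject).
#' @param adjustment residual adjustment, see [adjust_residuals()].
#' @param contrast optional q x p contrast matrix (or length-p vector). When
#'   supplied with `return_S = FALSE`, only the q x q projections C S C' are
#'   stored per response instead of the full p x p matrices, bounding memory
#'   for large V; the arithmetic is identical to the full path.
#' @param return_S keep the full p x p covariance per response.
#' @return object of class `swe_fit` with elements `beta` (p x V),
#'   `residuals`, `residuals_adjusted`, `S` (p x p x V array or NULL),
#'   `CSC` (q x q x V array when a contrast was given), `group_cov`,
#'   `variant`, `adjustment` and the design.
#' @export
swe_fit <- function(design, Y, variant = c("hom", "het"),
                    adjustment = c("S3", "S0", "S1", "S2"),
                    contrast = NULL, return_S = TRUE) {
  variant <- match.arg(variant)
  adjustment <- match.arg(adjustment)
  if (!return_S && is.null(contrast))
    stop("return_S = FALSE requires a contrast")
  Y <- .as_response(design, Y)
  ols <- fit_ols(design, Y)
  Eadj <- adjust_residuals(ols$residuals, design$hat, design$n, design$p,
                           adjustment)
  group_cov <- NULL
  if (variant == "hom") {
    group_cov <- estimate_group_covariance(design, Eadj)
    S_flat <- .swe_hom_flat(design, group_cov)
  } else {
    S_flat <- .swe_het_flat(design, Eadj)
  }
  CSC <- NULL
  if (!is.null(contrast)) {
    C <- .as_contrast(contrast, design$p)
    CSC <- array((C %x% C) %*% S_flat,
                 dim = c(nrow(C), nrow(C), ncol(S_flat)))
  }
  S <- if (return_S) .flat_to_array(S_flat, design$p) else NULL
  structure(list(
    design = design, beta = ols$beta, residuals = ols$residuals,
    residuals_adjusted = Eadj, S = S, S_flat = if (return_S) S_flat,
    CSC = CSC, contrast = if (!is.null(contrast)) .as_contrast(contrast, design$p),
    group_cov = group_cov, variant = variant, adjustment = adjustment
  ), class = "swe_fit")
}

#' @export
print.swe_fit <- function(x, ...) {
  cat("Sandwich-estimator fit (", x$variant, ", ", x$adjustment, "): ",
      x$design$m, " subjects, ", x$design$n, " observations, ",
      ncol(x$beta), " response(s)\n", sep = "")
  invisible(x)
}

## coerce a contrast to a q x p matrix with q = numerical rank
.as_contrast <- function(contrast, p) {
  C <- if (is.vector(contrast)) matrix(contrast, nrow = 1L) else
    as.matrix(contrast)
  if (ncol(C) != p)
    stop("contrast has ", ncol(C), " columns; design has p = ", p)
  qr_ <- qr(t(C))
  rk <- qr_$rank
  if (rk < 1L) stop("contrast has rank 0")
  if (rk < nrow(C)) {
    warning("contrast rows are linearly dependent; using the ", rk,
            " independent row(s)")
    C <- C[qr_$pivot[seq_len(rk)], , drop = FALSE]
  }
  C
}

#' Write per-group covariance estimates to CSV for audit
#'
#' One file per group holding the visit labels, the covariance estimate for
#' the selected response, and the pair counts.
#' @param group_cov an `swe_group_cov`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param response which response/voxel to export.
#' @return invisibly, the written paths.
#' @export
write_group_cov_csv <- function(group_cov, dir, prefix = "groupcov",
                                response = 1L) {
  stopifnot(inherits(group_cov, "swe_group_cov"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (g in group_cov$groups) {
    gc <- group_cov$est[[g]]
    Vm <- gc$V[, , response]
    df <- data.frame(visit = gc$visits, Vm, check.names = FALSE)
    names(df)[-1] <- paste0("V.", gc$visits)
    Mdf <- as.data.frame(gc$M)
    names(Mdf) <- paste0("m.", gc$visits)
    out <- cbind(df, Mdf)
    f <- file.path(dir, paste0(prefix, "_", gsub("[^A-Za-z0-9_.-]", "_", g),
                               ".csv"))
    utils::write.csv(out, f, row.names = FALSE)
    paths <- c(paths, f)
  }
  invisible(paths)
}
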