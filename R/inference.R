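#' Naive degrees of freedom
#'
#' Counts the pure between-subject columns of the design (columns constant
#' within every subject, e.g. group intercepts or a cross-sectional age
#' effect) and returns nu = m - p_B.
#'
#' @param design an `swe_design`.
#' @return object of class `swe_dof` with `nu` (positive integer), `method`
#'   and `p_B`.
#' @export
naive_dof <- function(design) {
  stopifnot(inherits(design, "swe_design"))
  p_B <- sum(.between_columns(design))
  nu <- design$m - p_B
  if (nu <= 0)
    stop("m - p_B = ", nu, " <= 0: more between-subject columns than subjects")
  structure(list(nu = nu, method = "naive", p_B = p_B), class = "swe_dof")
}

#' Effective degrees of freedom for a sandwich-covariance Wald test
#'
#' The robust covariance estimate C S C' is itself random, so referring the
#' Wald statistic to a chi-square (or an F with the OLS residual df) is
#' anti-conservative in small samples. This estimator moment-matches C S C'
#' to a Wishart distribution with `nu` effective degrees of freedom: every
#' element of C S C' is written as a quadratic form in the raw residuals
#' (block-diagonal over subjects; for the homogeneous variant the common
#' covariance estimator is linearised to its cross-moment form), its mean and
#' variance are evaluated under normality with the residual covariance
#' (I - H) Vhat (I - H)' implied by the variant's own plug-in covariance
#' estimate, and nu solves
#' nu = (tr(L)^2 + tr(L^2)) / sum_ab Var((C S C')_ab), with L the matched
#' mean. For q = 1 this is the scalar Satterthwaite match 2 E^2 / Var. For
#' the homogeneous variant in the one-group, one-observation-per-subject,
#' intercept-contrast case it gives exactly nu = m - 1, and nu grows
#' proportionally when the design is replicated. The heterogeneous variant
#' plugs in per-subject residual outer products, so its nu is itself noisy
#' — one more reason to prefer the homogeneous variant.
#'
#' The computation is split into a contrast-specific, response-independent
#' precomputation and a cheap per-response evaluation, so mass-univariate
#' use costs little beyond the fit itself.
#'
#' @param fit an `swe_fit`.
#' @param contrast q x p matrix or length-p vector; defaults to the contrast
#'   stored in the fit.
#' @return object of class `swe_dof` with `nu` (length-V numeric), `method`
#'   = "effective" and `clamped` (count of responses where nu fell below q
#'   and was clamped, with a warning).
#' @export
estimate_dof <- function(fit, contrast = NULL) {
  stopifnot(inherits(fit, "swe_fit"))
  if (is.null(contrast)) contrast <- fit$contrast
  if (is.null(contrast)) stop("no contrast supplied or stored in fit")
  C <- .as_contrast(contrast, fit$design$p)
  pre <- .dof_precompute(fit, C)
  nu <- .dof_evaluate(fit, pre)
  q <- nrow(C)
  bad <- !is.finite(nu) | nu <= 0
  if (any(bad))
    stop("degenerate contrast covariance: effective df undefined for ",
         sum(bad), " response(s)")
  clamped <- sum(nu < q)
  if (clamped > 0) {
    warning("effective df below contrast rank for ", clamped,
            " response(s); clamped to q = ", q)
    nu <- pmax(nu, q)
  }
  structure(list(nu = nu, method = "effective", clamped = clamped),
            class = "swe_dof")
}

## ---- response-independent pieces -------------------------------------------

## For each pair (a, b) of contrast rows, the per-subject symmetric matrices
## A_i such that (C S C')_ab = sum_i e_i' A_i e_i with e the *raw* residuals
## (residual-adjustment factors folded into A).  Subjects are partitioned
## into equivalence classes sharing identical blocks so complete balanced
## designs cost O(#groups), not O(m), per response.
.dof_precompute <- function(fit, C) {
  design <- fit$design
  p <- design$p
  q <- nrow(C)
  B <- design$XtX_inv
  AL <- design$X %*% B %*% t(C)                    # n x q, rows alpha_j
  fac <- .adjust_factors(design$hat, design$n, design$p, fit$adjustment)
  if (is.null(fac)) fac <- rep(1, design$n)

  pairs <- list()
  for (a in seq_len(q)) for (b in a:q)
    pairs[[length(pairs) + 1L]] <- c(a, b)

  subj <- list()
  for (i in seq_along(design$subjects)) {
    id <- design$subjects[i]
    r <- design$subj_rows[[id]]
    g <- design$subj_group[i]
    kap <- design$visit_idx[r]
    subj[[i]] <- list(id = id, rows = r, group = g, kap = kap,
                      X = design$X[r, , drop = FALSE], f = fac[r])
  }

  if (fit$variant == "hom") {
    ## weights W_g^{ab} = sym(D_g^{ab}) / M_g built from scattered alphas
    Wg <- list()
    for (g in design$groups) {
      K <- length(design$visit_levels[[g]])
      rowmap <- .group_rowmap(design, g)
      Ag <- array(0, dim = c(K, ncol(rowmap), q))
      for (a in seq_len(q)) {
        tmp <- matrix(0, K, ncol(rowmap))
        tmp[rowmap > 0L] <- AL[rowmap[rowmap > 0L], a]
        Ag[, , a] <- tmp
      }
      M <- fit$group_cov$est[[g]]$M
      Minv <- ifelse(M > 0L, 1 / M, 0)
      Wg[[g]] <- lapply(pairs, function(ab) {
        Da <- matrix(Ag[, , ab[1]], K)
        Db <- matrix(Ag[, , ab[2]], K)
        D <- Da %*% t(Db)
        ((D + t(D)) / 2) * Minv
      })
    }
    A_of <- function(s, j) {
      W <- Wg[[s$group]][[j]][s$kap, s$kap, drop = FALSE]
      W * tcrossprod(s$f)                          # fold adjustment
    }
  } else {
    A_of <- function(s, j) {
      a <- AL[s$rows, pairs[[j]][1]]
      b <- AL[s$rows, pairs[[j]][2]]
      D <- (tcrossprod(a, b) + tcrossprod(b, a)) / 2
      D * tcrossprod(s$f)
    }
  }
  A_list <- lapply(seq_along(subj), function(i)
    lapply(seq_along(pairs), function(j) A_of(subj[[i]], j)))

  ## equivalence classes: identical (group, visit pattern, X block, A blocks)
  ## -> per-response work done once per class (homogeneous variant only,
  ## where Vhat_i is common within the class too)
  classes <- NULL
  if (fit$variant == "hom") {
    key <- vapply(seq_along(subj), function(i)
      paste(subj[[i]]$group, paste(subj[[i]]$kap, collapse = ","),
            sep = "|"), character(1))
    cls <- split(seq_along(subj), key)
    classes <- lapply(cls, function(idx) {
      first <- idx[1]
      same <- all(vapply(idx, function(i)
        isTRUE(all.equal(subj[[i]]$X, subj[[first]]$X,
                         check.attributes = FALSE, tolerance = 0)) &&
        identical(subj[[i]]$f, subj[[first]]$f), logical(1)))
      list(members = idx, rep = first, uniform = same)
    })
  }
  list(C = C, q = q, pairs = pairs, subj = subj, A = A_list,
       classes = classes, B = B)
}

## ---- per-response evaluation ------------------------------------------------

.dof_evaluate <- function(fit, pre) {
  design <- fit$design
  p <- design$p
  q <- pre$q
  npair <- length(pre$pairs)
  Vresp <- ncol(fit$beta)
  nu <- numeric(Vresp)

  ## V-hat block extractor per subject per response
  if (fit$variant == "hom") {
    gcs <- fit$group_cov$est
    vhat <- function(s, v) gcs[[s$group]]$V[s$kap, s$kap, v, drop = FALSE][, , 1, drop = TRUE]
  } else {
    Eadj <- fit$residuals_adjusted
    vhat <- function(s, v) tcrossprod(Eadj[s$rows, v])
  }

  twop <- 2L * p
  Ip <- diag(p)
  units <- if (!is.null(pre$classes)) pre$classes
    else lapply(seq_along(pre$subj), function(i)
      list(members = i, rep = i, uniform = TRUE))
  for (v in seq_len(Vresp)) {
    ## assemble per-unit (class representative or subject) blocks
    T <- matrix(0, p, p)
    blocks <- vector("list", length(units))
    for (u in seq_along(units)) {
      un <- units[[u]]
      if (un$uniform) {
        s <- pre$subj[[un$rep]]
        Vi <- as.matrix(vhat(s, v))
        XtV <- crossprod(s$X, Vi)                  # p x k
        T <- T + length(un$members) * (XtV %*% s$X)
        blocks[[u]] <- list(kind = "uniform", w = length(un$members),
                            s = s, Vi = Vi, XtV = XtV)
      } else {
        ss <- lapply(un$members, function(i) pre$subj[[i]])
        Vis <- lapply(ss, vhat, v = v)
        XtVs <- mapply(function(s, Vi) crossprod(s$X, as.matrix(Vi)),
                       ss, Vis, SIMPLIFY = FALSE)
        for (j in seq_along(ss)) T <- T + XtVs[[j]] %*% ss[[j]]$X
        blocks[[u]] <- list(kind = "each", ss = ss, Vis = Vis, XtVs = XtVs,
                            members = un$members)
      }
    }
    K2 <- rbind(cbind(T, -Ip), cbind(-Ip, matrix(0, p, p)))

    lam <- matrix(0, q, q)
    vtot <- 0
    Wsum <- vector("list", npair)
    for (j in seq_len(npair)) Wsum[[j]] <- matrix(0, twop, twop)
    t1 <- numeric(npair); t2 <- numeric(npair); trL <- numeric(npair)

    add_unit <- function(s, Vi, XtV, A_js, w) {
      U <- s$X %*% pre$B                          # k x p
      UR <- U %*% XtV                             # U (X'V) -> k x k
      Sii <- Vi - UR - t(UR) + U %*% T %*% t(U)
      Z <- cbind(U, t(XtV))                       # k x 2p
      Psi <- Z %*% K2 %*% t(Z)
      for (j in seq_len(npair)) {
        A <- A_js[[j]]
        AV <- A %*% Vi
        trL[j] <<- trL[j] + w * sum(A * Sii)
        t1[j] <<- t1[j] + w * sum(AV * t(AV))
        t2[j] <<- t2[j] + 2 * w * sum((AV %*% A) * Psi)
        Wsum[[j]] <<- Wsum[[j]] + w * crossprod(Z, A %*% Z)
      }
    }

    for (u in seq_along(units)) {
      bl <- blocks[[u]]
      if (bl$kind == "uniform") {
        add_unit(bl$s, bl$Vi, bl$XtV, pre$A[[units[[u]]$rep]], bl$w)
      } else {
        for (jj in seq_along(bl$ss))
          add_unit(bl$ss[[jj]], as.matrix(bl$Vis[[jj]]), bl$XtVs[[jj]],
                   pre$A[[bl$members[jj]]], 1)
      }
    }

    for (j in seq_len(npair)) {
      ab <- pre$pairs[[j]]
      lam[ab[1], ab[2]] <- lam[ab[2], ab[1]] <- trL[j]
      t3 <- sum((Wsum[[j]] %*% K2) * t(Wsum[[j]] %*% K2))
      var_ab <- 2 * (t1[j] + t2[j] + t3)
      vtot <- vtot + var_ab * if (ab[1] == ab[2]) 1 else 2
    }
    num <- sum(diag(lam))^2 + sum(lam * lam)
    nu[v] <- num / vtot
  }
  nu
}

#' Wald test on a contrast
#'
#' Tests H0: C beta = 0 per response. The quadratic form
#' (C beta)' (C S C')^-1 (C beta), rescaled by (nu - q + 1)/(nu q), is
#' referred to an F(q, nu - q + 1) distribution, where nu is either the
#' moment-matched effective df (default) or the naive m - p_B. For q = 1 the
#' equivalent signed t statistic against t_nu is also returned, and one-sided
#' alternatives are available.
#'
#' @param fit an `swe_fit`.
#' @param contrast q x p matrix or length-p vector (defaults to the one
#'   stored in the fit).
#' @param dof "effective", "naive", an `swe_dof` object, or a numeric nu.
#' @param alternative for q = 1 only: "two.sided" (default), "greater",
#'   "less".
#' @return data frame of class `swe_test` with one row per response:
#'   `stat` (F scale), `df1`, `df2`, `nu`, `p`, and for q = 1 also `t`.
#' @export
wald_test <- function(fit, contrast = NULL,
                      dof = c("effective", "naive"),
                      alternative = c("two.sided", "greater", "less")) {
  stopifnot(inherits(fit, "swe_fit"))
  alternative <- match.arg(alternative)
  if (is.null(contrast)) contrast <- fit$contrast
  if (is.null(contrast)) stop("no contrast supplied or stored in fit")
  C <- .as_contrast(contrast, fit$design$p)
  q <- nrow(C)

  if (inherits(dof, "swe_dof")) {
    nu <- dof$nu
  } else if (is.numeric(dof)) {
    nu <- dof
  } else {
    dof <- match.arg(dof)
    nu <- if (dof == "naive") naive_dof(fit$design)$nu
          else estimate_dof(fit, C)$nu
  }
  Vresp <- ncol(fit$beta)
  nu <- rep_len(nu, Vresp)
  if (any(nu - q + 1 <= 0))
    stop("nu - q + 1 <= 0: contrast rank too high for the available df")

  cb <- C %*% fit$beta                                   # q x V
  CSC <- .contrast_cov(fit, C)                           # q^2 x V
  if (q == 1L) {
    csc <- as.numeric(CSC)
    if (any(csc <= 0))
      stop("contrast not estimable with this covariance (C S C' <= 0 for ",
           sum(csc <= 0), " response(s))")
    tt <- as.numeric(cb) / sqrt(csc)
    Fstat <- tt^2                                        # (nu-q+1)/(nu q) = 1
    p <- switch(alternative,
      two.sided = 2 * stats::pt(-abs(tt), df = nu),
      greater = stats::pt(tt, df = nu, lower.tail = FALSE),
      less = stats::pt(tt, df = nu))
    out <- data.frame(stat = Fstat, df1 = q, df2 = nu, nu = nu, p = p, t = tt)
  } else {
    if (alternative != "two.sided")
      stop("one-sided alternatives require a rank-1 contrast")
    Fstat <- numeric(Vresp)
    for (v in seq_len(Vresp)) {
      W <- matrix(CSC[, v], q, q)
      sol <- tryCatch(solve(W, cb[, v]), error = function(e) NULL)
      if (is.null(sol) || rcond(W) < 1e-14)
        stop("contrast not estimable with this covariance (singular C S C')")
      Fstat[v] <- ((nu[v] - q + 1) / (nu[v] * q)) * sum(cb[, v] * sol)
    }
    p <- stats::pf(Fstat, q, nu - q + 1, lower.tail = FALSE)
    out <- data.frame(stat = Fstat, df1 = q, df2 = nu - q + 1, nu = nu, p = p)
  }
  class(out) <- c("swe_test", class(out))
  out
}

## q^2 x V matrix of vec(C S C') per response, identical arithmetic for the
## full-S and contrast-wise storage paths
.contrast_cov <- function(fit, C) {
  if (!is.null(fit$CSC) && !is.null(fit$contrast) &&
      isTRUE(all.equal(C, fit$contrast, tolerance = 0,
                       check.attributes = FALSE))) {
    q <- nrow(C)
    return(matrix(fit$CSC, q * q, dim(fit$CSC)[3]))
  }
  if (is.null(fit$S_flat))
    stop("fit stores neither S nor a matching contrast projection")
  (C %x% C) %*% fit$S_flat
}

#' Multiplicity control over responses
#'
#' @param p_values numeric vector of p-values.
#' @param method "fdr" (Benjamini-Hochberg step-up, default) or
#'   "bonferroni".
#' @param level significance level after correction.
#' @return logical rejection mask.
#' @export
multiplicity_control <- function(p_values, method = c("fdr", "bonferroni"),
                                 level = 0.05) {
  method <- match.arg(method)
  if (!length(p_values)) stop("empty p-value vector")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = switch(method, fdr = "BH",
                                                   bonferroni = "bonferroni"))
  !is.na(adj) & adj <= level
}
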