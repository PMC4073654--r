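#' Largest complete-case subset of a longitudinal design
#'
#' The compound-symmetry test needs a rectangular (no-missingness) data
#' block. Dropping a rarely observed visit can retain many more subjects, so
#' "largest" involves a trade-off; this function searches all visit subsets
#' of size >= 2 and maximises n_complete * choose(#visits, 2) — the number
#' of subject-level covariance pairs the subset supports — breaking ties
#' toward more visits. The search is over the pooled visit categories (the
#' test treats the sample as a single group).
#'
#' @param design an `swe_design`.
#' @param data n x V response matrix (rows matching the design).
#' @return list with `design` and `data` restricted to the retained subjects
#'   and visits, plus `visits_used`, `n_complete` and the retained row
#'   indices `rows`.
#' @export
complete_case_subset <- function(design, data) {
  stopifnot(inherits(design, "swe_design"))
  data <- .as_response(design, data)
  visits <- sort(unique(design$visit))
  if (length(visits) < 2) stop("need at least 2 visit categories")
  ## subject x visit presence
  pres <- matrix(FALSE, design$m, length(visits),
                 dimnames = list(design$subjects, visits))
  for (i in seq_along(design$subjects)) {
    r <- design$subj_rows[[design$subjects[i]]]
    pres[i, match(design$visit[r], visits)] <- TRUE
  }
  best <- NULL
  nv <- length(visits)
  for (size in 2:nv) {
    combs <- utils::combn(nv, size)
    for (j in seq_len(ncol(combs))) {
      sel <- combs[, j]
      ncomp <- sum(rowSums(pres[, sel, drop = FALSE]) == size)
      if (ncomp < size + 1) next     # covariance would be singular
      score <- ncomp * choose(size, 2)
      if (is.null(best) || score > best$score ||
          (score == best$score && size > length(best$sel))) {
        best <- list(sel = sel, score = score, ncomp = ncomp)
      }
    }
  }
  if (is.null(best))
    stop("no visit subset of size >= 2 has enough complete subjects")
  vis_keep <- visits[best$sel]
  subj_keep <- design$subjects[rowSums(pres[, best$sel, drop = FALSE]) ==
                                 length(best$sel)]
  rows <- which(design$subject %in% subj_keep & design$visit %in% vis_keep)
  tab <- data.frame(subject = design$subject[rows],
                    group = design$group[rows],
                    visit = design$visit[rows],
                    time = design$time[rows])
  sub_design <- design_from_matrix(design$X[rows, , drop = FALSE], tab)
  list(design = sub_design, data = data[rows, , drop = FALSE],
       visits_used = vis_keep, n_complete = best$ncomp, rows = rows)
}

#' Box's test of compound symmetry (one response)
#'
#' Compound symmetry (all variances equal, all pairwise covariances equal)
#' is the assumption under which subject-dummy OLS and random-intercept
#' mixed models are valid. This test removes the supplied mean structure by
#' OLS, estimates a single pooled covariance matrix over visit categories
#' (treating all subjects as one group), and compares its determinant to
#' that of the best-fitting compound-symmetric matrix via the scaled
#' likelihood-ratio statistic
#' u = -(1 - c1) nu log(|S| / |S0|), c1 = k(k+1)^2 (2k-3) /
#' (6 nu (k-1)(k^2+k-4)), referred to chi-square with k(k+1)/2 - 2 df; the
#' statistic is reported on the F scale (u / df1 with df2 = Inf). The
#' covariance df nu is the complete-case subject count minus the number of
#' pure between-subject design columns.
#'
#' @param design an `swe_design` (complete cases over its visit set; run
#'   [complete_case_subset()] first when there is missingness).
#' @param y single response vector.
#' @return object of class `box_cs`: `statistic` (F scale), `df1`, `df2`
#'   (Inf), `chisq`, `p`, `n_complete`, `visits_used`, `cov` (the pooled
#'   covariance estimate).
#' @export
box_cs_test <- function(design, y) {
  stopifnot(inherits(design, "swe_design"))
  y <- .as_response(design, y)
  if (ncol(y) != 1) stop("box_cs_test takes a single response")
  visits <- sort(unique(design$visit))
  k <- length(visits)
  if (k < 2) stop("need at least 2 visits")
  cnt <- tapply(design$visit, design$subject, length)
  if (any(cnt != k)) stop("design is not complete-case; run complete_case_subset first")

  ols <- fit_ols(design, y)
  ## pooled one-group covariance over visit categories
  one <- .pool_as_one_group(design)
  gc <- estimate_group_covariance(one, ols$residuals)
  S <- gc$est[[1]]$V[, , 1]
  nu <- design$m - sum(.between_columns(design))
  if (nu < k + 1) stop("too few subjects (df ", nu, ") for ", k, " visits")
  st <- .box_stat_from_S(S, k, nu)
  structure(c(st, list(n_complete = design$m, visits_used = visits,
                       cov = S)),
            class = "box_cs")
}

## determinant-ratio statistic from a pooled k x k covariance with df nu
.box_stat_from_S <- function(S, k, nu) {
  dS <- det(S)
  if (!is.finite(dS) || dS <= 0) stop("singular covariance estimate")
  s2 <- mean(diag(S))
  r <- mean(S[upper.tri(S)]) / s2
  dS0 <- s2^k * (1 - r)^(k - 1) * (1 + (k - 1) * r)
  lr <- max(0, -nu * log(dS / dS0))
  c1 <- k * (k + 1)^2 * (2 * k - 3) / (6 * nu * (k - 1) * (k^2 + k - 4))
  u <- (1 - c1) * lr
  df1 <- k * (k + 1) / 2 - 2
  p <- stats::pchisq(u, df = df1, lower.tail = FALSE)
  list(statistic = u / df1, chisq = u, df1 = df1, df2 = Inf, p = p,
       sigma2 = s2, rho = r)
}

## relabel the design as a single group with pooled visit categories
.pool_as_one_group <- function(design) {
  tab <- data.frame(subject = design$subject, group = "all",
                    visit = design$visit, time = design$time)
  design_from_matrix(design$X, tab)
}

#' @export
print.box_cs <- function(x, ...) {
  cat("Box test of compound symmetry: F-scale statistic =",
      format(x$statistic, digits = 4), "on", x$df1,
      "df, p =", format.pval(x$p), "\n")
  cat(x$n_complete, "complete subjects over visits:",
      paste(x$visits_used, collapse = ", "), "\n")
  invisible(x)
}

#' Voxelwise compound-symmetry test map
#'
#' Runs [box_cs_test()] at every in-analysis voxel, applies a multiplicity
#' correction, and reports the fraction of surviving voxels. Per-voxel
#' numerical failures become NaN in the maps and are counted, not fatal.
#'
#' @param design an `swe_design` (missingness allowed; the complete-case
#'   subset is taken once for all voxels).
#' @param data n x V matrix of in-mask voxel time series (rows = scans), or
#'   the list returned by [read_images()].
#' @param correction "fdr" (default) or "bonferroni".
#' @param level significance level.
#' @return list with `F` and `p` vectors (length V), the rejection `mask`,
#'   `surviving_fraction`, `n_failed`, `n_complete` and `visits_used`.
#' @export
cs_test_image <- function(design, data, correction = c("fdr", "bonferroni"),
                          level = 0.05) {
  correction <- match.arg(correction)
  if (is.list(data) && !is.null(data$Y)) data <- data$Y
  data <- .as_response(design, data)
  if (ncol(data) < 1) stop("empty mask: no in-analysis voxels")
  cc <- complete_case_subset(design, data)
  V <- ncol(data)
  Fv <- rep(NA_real_, V)
  pv <- rep(NA_real_, V)
  n_failed <- 0L
  ## shared, voxel-independent work: one OLS fit and one pooled covariance
  ## pass over all voxels; only the determinant arithmetic is per voxel
  k <- length(cc$visits_used)
  ols <- fit_ols(cc$design, cc$data)
  one <- .pool_as_one_group(cc$design)
  gc <- estimate_group_covariance(one, ols$residuals)
  nu <- cc$design$m - sum(.between_columns(cc$design))
  for (v in seq_len(V)) {
    res <- tryCatch(.box_stat_from_S(gc$est[[1]]$V[, , v], k, nu),
                    error = function(e) NULL)
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      Fv[v] <- NaN; pv[v] <- NaN
    } else {
      Fv[v] <- res$statistic
      pv[v] <- res$p
    }
  }
  if (n_failed > 0)
    message("box_cs_test failed at ", n_failed, " voxel(s); set to NaN")
  ok <- is.finite(pv)
  mask <- rep(FALSE, V)
  if (any(ok))
    mask[ok] <- multiplicity_control(pv[ok], method = correction,
                                     level = level)
  list(F = Fv, p = pv, mask = mask,
       surviving_fraction = mean(mask[ok]),
       n_failed = n_failed, n_complete = cc$n_complete,
       visits_used = cc$visits_used)
}
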