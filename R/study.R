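#' Normal-approximation binomial band for a rejection rate
#'
#' The band within which the empirical rejection rate of an exactly valid
#' test at rate `p0` falls with the stated probability over `n_real`
#' independent realisations: p0 +/- z sqrt(p0 (1 - p0) / n_real).
#'
#' @param p0 true rejection probability (e.g. the nominal level).
#' @param n_real number of realisations.
#' @param level coverage of the band.
#' @return c(lo, hi) in percent.
#' @export
binomial_ci <- function(p0, n_real, level = 0.95) {
  stopifnot(p0 >= 0, p0 <= 1, n_real >= 1)
  z <- stats::qnorm((1 + level) / 2)
  half <- z * sqrt(p0 * (1 - p0) / n_real)
  c(lo = max(0, p0 - half) * 100, hi = min(1, p0 + half) * 100)
}

#' Analytic GLS/OLS relative efficiency per design column
#'
#' Ratio of the generalised-least-squares coefficient variance (the
#' minimum-variance benchmark, using the true per-subject covariance) to the
#' working-independence OLS coefficient variance, per column. A ratio of 1
#' means OLS loses nothing; splitting time-varying covariates into between-
#' and within-subject components drives the within-component ratio to 1
#' under compound symmetry.
#'
#' @param design an `swe_design`.
#' @param true_cov a [cov_structure()] (per-subject matrices derived from
#'   the design times) or a list of per-subject covariance matrices in
#'   `design$subjects` order.
#' @return named vector of per-column ratios (<= 1 up to rounding).
#' @export
relative_efficiency <- function(design, true_cov) {
  stopifnot(inherits(design, "swe_design"))
  p <- design$p
  meat <- matrix(0, p, p)
  info <- matrix(0, p, p)
  for (i in seq_along(design$subjects)) {
    r <- design$subj_rows[[design$subjects[i]]]
    Xi <- design$X[r, , drop = FALSE]
    Vi <- if (inherits(true_cov, "cov_structure"))
      cov_matrix(true_cov, design$time[r], design$subj_group[[i]])
    else as.matrix(true_cov[[i]])
    meat <- meat + crossprod(Xi, Vi) %*% Xi
    info <- info + crossprod(Xi, solve(Vi, Xi))
  }
  B <- design$XtX_inv
  var_ols <- diag(B %*% meat %*% B)
  var_gls <- diag(solve(info))
  stats::setNames(var_gls / var_ols, colnames(design$X))
}

#' Resolve a contrast keyword against a design
#'
#' Accepts a numeric vector/matrix (returned as is), a design column name
#' (tests that coefficient against 0), or `"diff:<colA>-<colB>"` (tests the
#' difference of two coefficients).
#' @param design an `swe_design`.
#' @param key numeric contrast or character keyword.
#' @export
resolve_contrast <- function(design, key) {
  if (is.numeric(key)) return(key)
  stopifnot(is.character(key), length(key) == 1)
  cn <- colnames(design$X)
  cvec <- rep(0, design$p)
  if (startsWith(key, "diff:")) {
    parts <- strsplit(sub("^diff:", "", key), "-", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !all(parts %in% cn))
      stop("cannot resolve contrast '", key, "'; columns are: ",
           paste(cn, collapse = ", "))
    cvec[match(parts[1], cn)] <- 1
    cvec[match(parts[2], cn)] <- -1
  } else {
    if (!key %in% cn)
      stop("unknown design column '", key, "'; columns are: ",
           paste(cn, collapse = ", "))
    cvec[match(key, cn)] <- 1
  }
  cvec
}

## parse "swe_hom_S3_eff" style method labels
.parse_method <- function(label) {
  if (is.function(label)) return(list(kind = "adapter", fn = label,
                                      label = "adapter"))
  parts <- strsplit(label, "_", fixed = TRUE)[[1]]
  if (parts[1] == "swe") {
    if (length(parts) != 4)
      stop("SwE method label must look like swe_hom_S3_eff: ", label)
    list(kind = "swe", variant = match.arg(parts[2], c("hom", "het")),
         adjustment = match.arg(parts[3], c("S0", "S1", "S2", "S3")),
         dof = match.arg(parts[4], c("eff", "naive")), label = label)
  } else if (label %in% c("n_ols", "ss_ols")) {
    list(kind = label, label = label)
  } else stop("unknown method: ", label)
}

#' Monte-Carlo rejection-rate study
#'
#' Simulates `realisations` independent datasets under a chosen design and
#' covariance structure (plus optional signal), applies each method to each
#' dataset, and tabulates rejection rates at the nominal level: false
#' positive rates for effect size 0, true positive rates otherwise. All
#' realisations of one setting are generated as the columns of a single
#' response matrix, so the estimators run in their vectorised
#' mass-univariate form.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{design}{`list(type = "balanced", m, k)` or
#'       `list(type = "adni", halvings = 0)`.}
#'     \item{cov}{preset name ("cs", "toeplitz", "het_groups",
#'       "het_visits") or `list(alpha, gamma, rho, psi)`.}
#'     \item{methods}{character vector of method labels
#'       (`swe_<hom|het>_<S0..S3>_<eff|naive>`, `n_ols`, `ss_ols`) and/or
#'       functions `(design, Y, contrast, alpha) -> p-values` used as
#'       plug-in adapters.}
#'     \item{contrasts}{named list of contrast keywords or numeric vectors
#'       (see [resolve_contrast()]). For `ss_ols` the contrast's within-
#'       subject weights define the stage-1 summary and its group pattern
#'       the stage-2 test.}
#'     \item{effect_sizes}{numeric vector; default 0.}
#'     \item{realisations}{per setting; >= 100.}
#'     \item{seed}{master seed; per-setting substreams are derived from it.}
#'     \item{alpha}{nominal level, default 0.05.}
#'   }
#' @return data frame (class `swe_simsummary`): one row per method x
#'   contrast x effect size with the rejection `rate` (percent), the
#'   binomial CI around the observed rate, the validity `band` around the
#'   nominal level (null rows), realisation and failure counts, and the
#'   substream seed.
#' @export
run_rejection_study <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  alpha <- config$alpha %||% 0.05
  nreal <- config$realisations
  if (is.null(nreal) || nreal < 100) stop("need realisations >= 100")
  seed <- config$seed %||% 1L
  effect_sizes <- config$effect_sizes %||% 0

  dsg <- config$design
  design <- switch(dsg$type %||% "balanced",
    balanced = build_balanced_design(dsg$m, dsg$k, dsg$degree %||% 2),
    adni = {
      built <- build_adni_like_design(seed = .derive_seed(seed, 9001))
      tab <- built$table
      h <- dsg$halvings %||% 0
      for (j in seq_len(h))
        tab <- halve_subjects(tab, seed = .derive_seed(seed, 9100 + j))
      spec <- list(term_intercept(TRUE), term_covariate("age_cross", TRUE),
                   term_covariate("age_long", TRUE),
                   term_covariate("accel", TRUE))
      build_design(tab, spec)
    },
    stop("unknown design type"))

  params <- if (inherits(config$cov, "cov_structure")) config$cov
    else if (is.character(config$cov))
      .preset_cov(config$cov,
                  if ((dsg$type %||% "balanced") == "adni") "adni" else "balanced")
    else do.call(cov_structure, config$cov)
  ## presets name groups A/B or N/MCI/AD; align to the actual design groups
  if (length(params$alpha) > 1 &&
      !all(design$groups %in% names(params$alpha))) {
    if (length(params$alpha) == length(design$groups))
      names(params$alpha) <- design$groups
    else stop("alpha names do not match design groups")
  }

  contrasts <- config$contrasts
  if (is.null(names(contrasts)))
    names(contrasts) <- paste0("c", seq_along(contrasts))
  methods <- lapply(config$methods, .parse_method)

  rows <- list()
  setting <- 0L
  for (es in effect_sizes) {
    setting <- setting + 1L
    sub_seed <- .derive_seed(seed, setting)
    ## the signal is added to the first group only, so that both pure
    ## visit-effect and group-difference contrasts see a non-null effect
    es_vec <- stats::setNames(c(es, rep(0, length(design$groups) - 1)),
                              design$groups)
    Y <- simulate_responses(design, params, effect_size = es_vec, V = nreal,
                            seed = sub_seed)
    for (cname in names(contrasts)) {
      C <- resolve_contrast(design, contrasts[[cname]])
      for (meth in methods) {
        pv <- tryCatch(.method_pvalues(meth, design, Y, C, alpha),
                       error = function(e) {
                         warning("method ", meth$label, " failed: ",
                                 conditionMessage(e))
                         rep(NA_real_, nreal)
                       })
        nfail <- sum(!is.finite(pv))
        rate <- mean(pv <= alpha, na.rm = TRUE) * 100
        ci <- binomial_ci(rate / 100, sum(is.finite(pv)))
        band <- binomial_ci(alpha, sum(is.finite(pv)))
        rows[[length(rows) + 1L]] <- data.frame(
          method = meth$label, contrast = cname, effect_size = es,
          type = if (es == 0) "FPR" else "TPR", rate = rate,
          ci_lo = unname(ci[1]), ci_hi = unname(ci[2]),
          band_lo = unname(band[1]), band_hi = unname(band[2]),
          n_real = nreal, n_failed = nfail, alpha = alpha, seed = sub_seed)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("swe_simsummary", class(out))
  out
}

.method_pvalues <- function(meth, design, Y, C, alpha) {
  switch(meth$kind,
    swe = {
      fit <- swe_fit(design, Y, variant = meth$variant,
                     adjustment = meth$adjustment, contrast = C,
                     return_S = FALSE)
      wald_test(fit, C,
                dof = if (meth$dof == "naive") "naive" else "effective")$p
    },
    n_ols = n_ols_fit(design, Y, C)$p,
    ss_ols = {
      ## split the contrast into a stage-1 within summary and a stage-2
      ## group pattern: the summary uses |C| weights on within columns and
      ## the group signs are recovered from the columns' group membership
      Cm <- .as_contrast(C, design$p)
      if (nrow(Cm) != 1)
        stop("ss_ols supports rank-1 contrasts in the study harness")
      cvec <- as.numeric(Cm)
      nz <- which(cvec != 0)
      if (!length(nz)) stop("empty contrast")
      grp_of_col <- .column_group(design)
      gsign <- rep(0, length(design$groups))
      for (j in nz) {
        g <- grp_of_col[j]
        if (is.na(g)) stop("ss_ols needs group-specific contrast columns")
        gsign[match(g, design$groups)] <- sign(cvec[j])
      }
      within <- abs(cvec)
      ss_ols_fit(design, Y, within, group_contrast = gsign)$test$p
    },
    adapter = meth$fn(design, Y, C, alpha))
}

## group membership of each design column (NA when shared across groups)
.column_group <- function(design) {
  vapply(seq_len(design$p), function(j) {
    nzrows <- design$X[, j] != 0
    g <- unique(design$group[nzrows])
    if (length(g) == 1) g else NA_character_
  }, character(1))
}

#' Qualitative validity code for a simulated rejection rate
#'
#' @param rate empirical rate in percent.
#' @param band c(lo, hi) validity band in percent.
#' @return "accurate", "liberal" or "conservative".
#' @export
fpr_code <- function(rate, band) {
  if (rate > band[2]) "liberal"
  else if (rate < band[1]) "conservative"
  else "accurate"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## deterministic 31-bit substream seed
.derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + as.numeric(i) * 16807) %%
               2147483647)
}
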