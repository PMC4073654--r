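#' Covariance-structure parameters
#'
#' Parameterises the within-subject covariance used by the data generator:
#' var(y_ik) = alpha_g (1 + gamma t_k) and
#' corr(y_ik, y_ik') = rho (1 - psi |t_k - t_k'|). gamma and psi are per
#' time unit (per visit for the balanced designs, per year for the
#' ADNI-like design). Setting gamma = psi = 0 gives compound symmetry with
#' correlation rho; rho = 1 with psi > 0 gives a linearly decaying
#' (Toeplitz-like) correlation.
#'
#' @param alpha per-group variance scale; a named vector (names = group
#'   labels) or a single value for all groups.
#' @param gamma variance slope per time unit.
#' @param rho correlation level.
#' @param psi correlation decay per time unit (>= 0).
#' @export
cov_structure <- function(alpha = 1, gamma = 0, rho = 0, psi = 0) {
  stopifnot(all(alpha > 0), psi >= 0, abs(rho) <= 1)
  structure(list(alpha = alpha, gamma = gamma, rho = rho, psi = psi),
            class = "cov_structure")
}

## preset parameter rows used across the simulation studies
.preset_cov <- function(name, design = c("balanced", "adni")) {
  design <- match.arg(design)
  if (design == "balanced") {
    switch(name,
      cs = cov_structure(alpha = c(A = 1, B = 1), rho = 0.95),
      toeplitz = cov_structure(alpha = c(A = 1, B = 1), rho = 1, psi = 0.1),
      het_groups = cov_structure(alpha = c(A = 1, B = 2)),
      het_visits = cov_structure(alpha = c(A = 1, B = 1), gamma = 1),
      stop("unknown covariance preset: ", name))
  } else {
    a3 <- function(n, m, d) c(N = n, MCI = m, AD = d)
    switch(name,
      cs = cov_structure(alpha = a3(1, 1, 1), rho = 0.95),
      toeplitz = cov_structure(alpha = a3(1, 1, 1), rho = 1, psi = 0.2),
      het_groups = cov_structure(alpha = a3(1, 2, 3)),
      het_visits = cov_structure(alpha = a3(1, 1, 1), gamma = 2),
      stop("unknown covariance preset: ", name))
  }
}

#' Within-subject covariance matrix for a set of measurement times
#'
#' @param params a [cov_structure()].
#' @param times measurement times of the visits.
#' @param group group label (selects `alpha`).
#' @return k x k covariance matrix; if the decaying correlation makes the
#'   assembled matrix indefinite it is spectrally repaired with a warning.
#' @export
cov_matrix <- function(params, times, group = NULL) {
  stopifnot(inherits(params, "cov_structure"), all(is.finite(times)))
  a <- params$alpha
  if (length(a) > 1 || !is.null(names(a))) {
    if (is.null(group) || !group %in% names(a))
      stop("group label needed to select alpha")
    a <- a[[group]]
  }
  vv <- a * (1 + params$gamma * times)
  if (any(vv <= 0))
    stop("non-positive variance: gamma * t < -1 at some visit")
  dt <- abs(outer(times, times, "-"))
  corr <- params$rho * (1 - params$psi * dt)
  diag(corr) <- 1
  V <- corr * sqrt(outer(vv, vv))
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev))) {
    warning("assembled covariance indefinite; applying spectral repair")
    V <- psd_repair(V)
    attributes(V)$repaired <- NULL
  }
  V
}

#' Balanced two-group longitudinal design
#'
#' m subjects in two groups of equal size (for odd m, group A gets the extra
#' subject), each observed at k visits at times 0, 1, ..., k-1 (so
#' per-visit covariance parameters are per visit unit). The model contains,
#' for each group, an intercept plus linear and quadratic visit effects
#' coded with orthogonal polynomials.
#'
#' @param m subject count (>= 4).
#' @param k visits per subject (>= 3 for the default quadratic model).
#' @param degree polynomial degree of the visit effects.
#' @return an `swe_design`.
#' @export
build_balanced_design <- function(m, k, degree = 2) {
  stopifnot(m >= 4, k >= 2)
  if (k <= degree)
    stop("k = ", k, " visits cannot support a degree-", degree, " polynomial")
  mA <- ceiling(m / 2)
  subj <- sprintf("s%03d", seq_len(m))
  tab <- data.frame(
    subject = rep(subj, each = k),
    group = rep(c(rep("A", mA), rep("B", m - mA)), each = k),
    visit = rep(paste0("v", seq_len(k)), m),
    time = rep(seq_len(k) - 1, m)
  )
  spec <- list(term_intercept(by_group = TRUE),
               term_time_poly(degree = degree, by_group = TRUE))
  build_design(tab, spec)
}

#' Per-visit subject counts of the emulated three-group study
#'
#' Scanning-visit counts (months 0-36) for the Normal control, MCI and AD
#' groups of the motivating study: 817 subjects, 3314 scans in total; AD
#' subjects were not scanned at months 18 and 36 and Normal controls not at
#' month 18 by protocol.
#' @return integer matrix, rows = months (0, 6, 12, 18, 24, 36), columns =
#'   groups (N, MCI, AD); NA marks visits not in a group's protocol.
#' @export
adni_visit_counts <- function() {
  m <- rbind(
    `0`  = c(229, 400, 188),
    `6`  = c(208, 346, 159),
    `12` = c(196, 326, 138),
    `18` = c(NA, 286, NA),
    `24` = c(172, 244, 105),
    `36` = c(147, 170, NA)
  )
  colnames(m) <- c("N", "MCI", "AD")
  m
}

#' Unbalanced three-group design emulating the motivating study
#'
#' Builds a long table whose per-visit marginal subject counts match the
#' supplied table exactly: every subject has a baseline scan, and for each
#' follow-up visit the attending subjects are drawn uniformly at random
#' (missingness is not forced to be monotone, matching the non-monotone
#' protocol of the emulated study). Baseline ages are drawn per group
#' (defaults: N 76.0 +/- 5.0, MCI 74.8 +/- 7.4, AD 75.4 +/- 7.5 years). The
#' model has, per group: an intercept, the centred subject-mean age
#' (cross-sectional age effect), the subject-centred age (longitudinal
#' visit effect) and their interaction (acceleration) — 12 columns.
#'
#' @param counts per-visit subject counts (rows = months, columns = groups);
#'   defaults to [adni_visit_counts()].
#' @param age_mean,age_sd named per-group baseline-age parameters in years.
#' @param seed optional integer seed (local to this call).
#' @return list with the `swe_design` in `design`, the long `table` (with
#'   the derived age covariates) and the per-group subject ids `subjects`.
#' @export
build_adni_like_design <- function(counts = adni_visit_counts(),
                                   age_mean = c(N = 76.0, MCI = 74.8, AD = 75.4),
                                   age_sd = c(N = 5.0, MCI = 7.4, AD = 7.5),
                                   seed = NULL) {
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(seed)
  }
  months <- as.numeric(rownames(counts))
  groups <- colnames(counts)
  if (any(months != sort(months)) || months[1] != 0)
    stop("counts must start at baseline month 0")
  tabs <- list()
  subj_by_group <- list()
  for (g in groups) {
    cnt <- counts[, g]
    base <- cnt[1]
    if (is.na(base)) stop("group ", g, " has no baseline count")
    extra <- cnt[-1]
    if (any(extra[!is.na(extra)] > base))
      stop("group ", g, ": a follow-up count exceeds the baseline count")
    ids <- sprintf("%s%04d", g, seq_len(base))
    subj_by_group[[g]] <- ids
    pres <- matrix(FALSE, base, length(months))
    pres[, 1] <- TRUE
    for (j in seq_along(extra)) {
      if (is.na(extra[j]) || extra[j] == 0) next
      pres[sample.int(base, extra[j]), j + 1] <- TRUE
    }
    age0 <- stats::rnorm(base, age_mean[[g]], age_sd[[g]])
    idx <- which(pres, arr.ind = TRUE)
    tabs[[g]] <- data.frame(
      subject = ids[idx[, 1]],
      group = g,
      visit = paste0("m", months[idx[, 2]]),
      time = months[idx[, 2]] / 12,
      age = age0[idx[, 1]] + months[idx[, 2]] / 12
    )
  }
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL
  sp <- split_covariate(tab$age, tab$subject, centre_between = TRUE)
  tab$age_cross <- sp$between
  tab$age_long <- sp$within
  tab$accel <- sp$between * sp$within
  spec <- list(term_intercept(by_group = TRUE),
               term_covariate("age_cross", by_group = TRUE),
               term_covariate("age_long", by_group = TRUE),
               term_covariate("accel", by_group = TRUE))
  list(design = build_design(tab, spec), table = tab,
       subjects = subj_by_group)
}

#' Halve each group of a long table at random
#'
#' Keeps floor(m_g / 2) subjects per group; used to emulate the nested
#' sub-studies obtained by iteratively discarding half of the subjects.
#' @param table long table as returned by [build_adni_like_design()].
#' @param seed optional integer seed (local to this call).
#' @return the reduced long table.
#' @export
halve_subjects <- function(table, seed = NULL) {
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(seed)
  }
  subj <- unique(table[, c("subject", "group")])
  keep <- unlist(lapply(split(subj$subject, subj$group),
                        function(ids) sample(ids, floor(length(ids) / 2))))
  table[table$subject %in% keep, , drop = FALSE]
}

#' Simulate correlated longitudinal responses
#'
#' Each observation starts as an independent standard normal draw; each
#' subject's vector is then premultiplied by the lower-triangular Cholesky
#' factor of its covariance matrix (restricted to its observed visits).
#' Optionally a signal proportional to the subject-centred time is added
#' (a pure within-subject "visit" effect), scaled per group.
#'
#' @param design an `swe_design`.
#' @param params a [cov_structure()].
#' @param effect_size scalar, or named per-group vector, multiplying the
#'   subject-centred time; 0 gives null data.
#' @param V number of independent response replicates (columns).
#' @param seed optional integer seed (local to this call).
#' @return n x V response matrix.
#' @export
simulate_responses <- function(design, params, effect_size = 0, V = 1,
                               seed = NULL) {
  stopifnot(inherits(design, "swe_design"), inherits(params, "cov_structure"))
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(seed)
  }
  n <- design$n
  Z <- matrix(stats::rnorm(n * V), n, V)
  Y <- matrix(0, n, V)
  ## group subjects sharing (group, time pattern) to reuse Cholesky factors
  key <- vapply(design$subjects, function(id) {
    r <- design$subj_rows[[id]]
    paste(design$subj_group[[id]], paste(design$time[r], collapse = ","),
          sep = "|")
  }, character(1))
  for (kk in unique(key)) {
    ids <- design$subjects[key == kk]
    r1 <- design$subj_rows[[ids[1]]]
    L <- t(chol(cov_matrix(params, design$time[r1],
                           design$subj_group[[ids[1]]])))
    k <- length(r1)
    rows <- unlist(design$subj_rows[ids], use.names = FALSE)
    Zc <- matrix(Z[rows, , drop = FALSE], nrow = k)   # k x (m_c * V)
    Y[rows, ] <- matrix(L %*% Zc, nrow = length(rows))
  }
  if (any(effect_size != 0)) {
    es <- effect_size
    if (is.null(names(es))) es <- stats::setNames(rep(es[1], length(design$groups)),
                                                  design$groups)
    ct <- design$time - stats::ave(design$time, design$subject)
    Y <- Y + ct * es[design$group]
  }
  Y
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
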