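#' Longitudinal design construction
#'
#' `build_design()` turns a long-format observation table (one row per scan /
#' measurement occasion) into a validated longitudinal design object holding
#' the stacked design matrix together with the subject, group, visit and time
#' structure that all estimators in this package rely on.
#'
#' Rows are canonicalised to (subject, time, visit) order so that every
#' subject's observations form a contiguous block; all downstream block
#' indexing depends on this. Visit categories are taken as supplied
#' categorical labels (they are *not* inferred from times): the homogeneous
#' covariance estimator matches residuals across subjects by visit category,
#' so labels must be coded consistently within each group. Times are carried
#' separately and are used for covariance generation and polynomial bases.
#'
#' @param long_table data frame with columns `subject`, `group`, `visit`,
#'   `time` plus any covariate columns referenced by `model_spec`.
#' @param model_spec list of term descriptors created by [term_intercept()],
#'   [term_covariate()] and [term_time_poly()]. Terms are expanded in the
#'   given order; `by_group = TRUE` terms produce one column per group
#'   (group-major ordering).
#' @return an object of class `swe_design`: a list with the grand design
#'   matrix `X` (n x p), the per-row `subject`, `group`, `visit`, `time`
#'   vectors, counts `m`, `n`, `p`, per-subject row indices `subj_rows`,
#'   per-group visit level sets `visit_levels`, the per-row visit index
#'   `visit_idx` (position of the row's visit within its group's level set),
#'   and cached `XtX_inv` and hat-matrix diagonals `hat`.
#' @examples
#' tab <- data.frame(subject = rep(c("a", "b"), each = 2),
#'                   group = "g1", visit = rep(c("v1", "v2"), 2),
#'                   time = rep(0:1, 2))
#' d <- build_design(tab, list(term_intercept(by_group = FALSE)))
#' d$m; d$n; d$p
#' @export
build_design <- function(long_table, model_spec) {
  stopifnot(is.data.frame(long_table))
  need <- c("subject", "group", "visit", "time")
  miss <- setdiff(need, names(long_table))
  if (length(miss))
    stop("long_table is missing required column(s): ",
         paste(miss, collapse = ", "))
  tab <- as.data.frame(long_table)
  tab$subject <- as.character(tab$subject)
  tab$group <- as.character(tab$group)
  tab$visit <- as.character(tab$visit)
  tab$time <- as.numeric(tab$time)
  if (anyNA(tab$subject) || anyNA(tab$group) || anyNA(tab$visit) ||
      any(!is.finite(tab$time)))
    stop("subject/group/visit/time must be complete and time finite")

  ## canonical row order
  ord <- order(tab$subject, tab$time, tab$visit)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL

  if (anyDuplicated(paste(tab$subject, tab$visit, sep = "\r")))
    stop("duplicated (subject, visit) pairs found")
  gps <- tapply(tab$group, tab$subject, function(g) length(unique(g)))
  if (any(gps > 1))
    stop("group varies within subject: ",
         paste(names(gps)[gps > 1], collapse = ", "))

  X <- .expand_terms(tab, model_spec)
  .new_design(X, tab, orig_order = ord)
}

#' Declare an intercept term
#' @param by_group one intercept column per group (default) or a single one.
#' @export
term_intercept <- function(by_group = TRUE)
  list(type = "intercept", by_group = isTRUE(by_group))

#' Declare a numeric covariate term
#'
#' The covariate enters as supplied; use [split_covariate()] beforehand to
#' create separate between- and within-subject columns in the table.
#' @param var column name in the long table.
#' @param by_group interact the covariate with group membership.
#' @export
term_covariate <- function(var, by_group = FALSE)
  list(type = "covariate", var = var, by_group = isTRUE(by_group))

#' Declare orthogonal-polynomial time effects
#' @param degree polynomial degree (1 = linear, 2 = adds quadratic, ...).
#' @param by_group separate polynomial effects per group (default).
#' @export
term_time_poly <- function(degree = 2, by_group = TRUE)
  list(type = "time_poly", degree = as.integer(degree),
       by_group = isTRUE(by_group))

.expand_terms <- function(tab, model_spec) {
  if (!length(model_spec)) stop("empty model_spec")
  n <- nrow(tab)
  groups <- sort(unique(tab$group))
  cols <- list()
  for (tm in model_spec) {
    base <- switch(tm$type,
      intercept = {
        mat <- matrix(1, n, 1)
        colnames(mat) <- "intercept"
        mat
      },
      covariate = {
        if (!tm$var %in% names(tab)) stop("unknown covariate: ", tm$var)
        v <- as.numeric(tab[[tm$var]])
        if (any(!is.finite(v))) stop("non-finite covariate: ", tm$var)
        mat <- matrix(v, n, 1)
        colnames(mat) <- tm$var
        mat
      },
      time_poly = {
        deg <- tm$degree
        ## orthonormal basis over the observed times; any orthonormal basis
        ## over the visit grid gives identical test statistics
        if (isTRUE(tm$by_group)) {
          mat <- matrix(0, n, deg)
          for (g in groups) {
            idx <- tab$group == g
            if (length(unique(tab$time[idx])) <= deg)
              stop("time_poly degree ", deg,
                   " needs more distinct times in group ", g)
            mat[idx, ] <- stats::poly(tab$time[idx], degree = deg)
          }
        } else {
          if (length(unique(tab$time)) <= deg)
            stop("time_poly degree ", deg, " needs more distinct times")
          mat <- stats::poly(tab$time, degree = deg)
        }
        colnames(mat) <- paste0("time", seq_len(deg))
        mat
      },
      stop("unknown term type: ", tm$type)
    )
    if (isTRUE(tm$by_group) && tm$type != "time_poly") {
      for (g in groups) {
        gm <- base * (tab$group == g)
        colnames(gm) <- paste0(colnames(base), ".", g)
        cols[[length(cols) + 1L]] <- gm
      }
    } else if (isTRUE(tm$by_group) && tm$type == "time_poly") {
      ## time_poly by_group already computed per group rows; split columns
      for (g in groups) {
        gm <- base * (tab$group == g)
        colnames(gm) <- paste0(colnames(base), ".", g)
        cols[[length(cols) + 1L]] <- gm
      }
    } else {
      cols[[length(cols) + 1L]] <- base
    }
  }
  do.call(cbind, cols)
}

## shared constructor/validator for both build paths
.new_design <- function(X, tab, orig_order = seq_len(nrow(tab))) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  p <- ncol(X)
  if (n != nrow(tab)) stop("X rows do not match structure table")
  if (p >= n) stop("design has p >= n (", p, " >= ", n, ")")
  sv <- svd(X, nu = 0, nv = 0)$d
  if (sv[length(sv)] <= 1e-10 * sv[1])
    stop("design matrix is rank deficient (relative singular value <= 1e-10)")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))

  subj_rows <- split(seq_len(n), tab$subject)
  subjects <- names(subj_rows)
  subj_group <- vapply(subj_rows, function(r) tab$group[r[1]], character(1))
  groups <- sort(unique(tab$group))
  visit_levels <- lapply(groups, function(g) {
    idx <- tab$group == g
    ## order visit categories by their median time, then label
    vs <- unique(tab$visit[idx])
    tt <- vapply(vs, function(v)
      stats::median(tab$time[idx & tab$visit == v]), numeric(1))
    vs[order(tt, vs)]
  })
  names(visit_levels) <- groups
  visit_idx <- integer(n)
  for (g in groups) {
    idx <- tab$group == g
    visit_idx[idx] <- match(tab$visit[idx], visit_levels[[g]])
  }

  XtX <- crossprod(X)
  XtX_inv <- chol2inv(chol(XtX))
  hat <- rowSums((X %*% XtX_inv) * X)

  structure(list(
    X = X, subject = tab$subject, group = tab$group, visit = tab$visit,
    time = tab$time, m = length(subjects), n = n, p = p,
    subjects = subjects, groups = groups, subj_rows = subj_rows,
    subj_group = subj_group, visit_levels = visit_levels,
    visit_idx = visit_idx, XtX = XtX, XtX_inv = XtX_inv, hat = hat,
    input_order = orig_order
  ), class = "swe_design")
}

#' Build a design from an explicit numeric design matrix
#'
#' Alternative entry point matching the CSV interface where the design matrix
#' is supplied directly alongside a structure table.
#' @param X numeric n x p matrix.
#' @param structure data frame with `subject`, `group`, `visit`, `time`
#'   columns, one row per row of `X` (same order).
#' @export
design_from_matrix <- function(X, structure) {
  stopifnot(is.data.frame(structure))
  need <- c("subject", "group", "visit", "time")
  if (length(setdiff(need, names(structure))))
    stop("structure table needs subject, group, visit, time columns")
  tab <- structure
  tab$subject <- as.character(tab$subject)
  tab$group <- as.character(tab$group)
  tab$visit <- as.character(tab$visit)
  tab$time <- as.numeric(tab$time)
  ord <- order(tab$subject, tab$time, tab$visit)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  X <- as.matrix(X)[ord, , drop = FALSE]
  if (anyDuplicated(paste(tab$subject, tab$visit, sep = "\r")))
    stop("duplicated (subject, visit) pairs found")
  gps <- tapply(tab$group, tab$subject, function(g) length(unique(g)))
  if (any(gps > 1)) stop("group varies within subject")
  .new_design(X, tab, orig_order = ord)
}

#' Reorder scan-ordered responses to the design's canonical row order
#'
#' Designs canonicalise their row order at construction; responses supplied
#' in the order of the original table rows (e.g. scan order of an image
#' series) must be permuted accordingly before fitting.
#' @param design an `swe_design`.
#' @param Y responses in original input-row order.
#' @export
align_scans <- function(design, Y) {
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1L)
  Y <- as.matrix(Y)
  if (nrow(Y) != design$n)
    stop("response has ", nrow(Y), " rows; design has ", design$n)
  Y[design$input_order, , drop = FALSE]
}

#' Read a long-format CSV
#'
#' Required columns: `subject,group,visit,time`; every other column is
#' treated as a covariate or response. Header row mandatory, UTF-8.
#' @param path file path.
#' @export
read_long_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  need <- c("subject", "group", "visit", "time")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("CSV is missing required column(s): ", paste(miss, collapse = ", "))
  tab
}

#' Split a covariate into between- and within-subject components
#'
#' A time-varying covariate confounds two very different effects: a
#' cross-sectional (between-subject) effect of its subject mean and a
#' longitudinal (within-subject) effect of its deviation from that mean.
#' Entering both components as separate predictors avoids this confound and
#' makes the working-independence OLS estimator of the within-subject effect
#' fully efficient under compound symmetry.
#'
#' @param values numeric length-n covariate.
#' @param subject_id length-n subject labels.
#' @param centre_between subtract the grand mean from the between component
#'   (recommended whenever intercepts are interpreted).
#' @return list with `between` and `within` length-n vectors; the within
#'   component sums to zero within every subject by construction.
#' @export
split_covariate <- function(values, subject_id, centre_between = FALSE) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("values must be finite")
  subject_id <- as.character(subject_id)
  mu <- stats::ave(values, subject_id)
  within <- values - mu
  if (all(within == 0))
    warning("covariate is constant within every subject; within component is 0")
  between <- if (isTRUE(centre_between)) mu - mean(values) else mu
  list(between = between, within = within)
}

#' Hat-matrix diagonals of a design
#'
#' @param design an `swe_design`.
#' @return length-n vector of leverages, in (0, 1], summing to p.
#' @export
hat_diagonals <- function(design) {
  stopifnot(inherits(design, "swe_design"))
  design$hat
}

#' @export
print.swe_design <- function(x, ...) {
  cat("Longitudinal design: m =", x$m, "subjects,", "n =", x$n,
      "observations, p =", x$p, "columns,", length(x$groups), "group(s)\n")
  kk <- vapply(x$visit_levels, length, integer(1))
  cat("visit categories per group:",
      paste(sprintf("%s: %d", names(kk), kk), collapse = ", "), "\n")
  invisible(x)
}

## internal: count of pure between-subject columns (constant within subject)
.between_columns <- function(design) {
  X <- design$X
  const <- rep(TRUE, ncol(X))
  for (r in design$subj_rows) {
    if (length(r) > 1L) {
      blk <- X[r, , drop = FALSE]
      rng <- apply(blk, 2L, function(col) max(col) - min(col))
      const <- const & (rng == 0)
    }
  }
  const
}

## internal: coerce responses to an n x V double matrix
.as_response <- function(design, Y) {
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1L)
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (nrow(Y) != design$n)
    stop("response has ", nrow(Y), " rows; design has ", design$n)
  Y
}
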