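## fixtures are built in code; nothing is stored on disk

## m subjects, one observation each, intercept-only model
one_obs_design <- function(m) {
  tab <- data.frame(subject = sprintf("s%03d", seq_len(m)), group = "g",
                    visit = "v1", time = 0)
  build_design(tab, list(term_intercept(by_group = FALSE)))
}

## complete one-group design, k visits at times 0..k-1, intercept + linear
simple_long_design <- function(m, k) {
  tab <- data.frame(subject = rep(sprintf("s%03d", seq_len(m)), each = k),
                    group = "g",
                    visit = rep(paste0("v", seq_len(k)), m),
                    time = rep(seq_len(k) - 1, m))
  build_design(tab, list(term_intercept(FALSE), term_time_poly(1, FALSE)))
}

## same rows but every subject its own group
per_subject_groups <- function(design) {
  tab <- data.frame(subject = design$subject, group = design$subject,
                    visit = design$visit, time = design$time)
  design_from_matrix(design$X, tab)
}

## brute-force heterogeneous sandwich for one response (independent oracle)
brute_swe_het <- function(design, e) {
  B <- solve(crossprod(design$X))
  meat <- matrix(0, design$p, design$p)
  for (r in design$subj_rows) {
    Xi <- design$X[r, , drop = FALSE]
    gi <- crossprod(Xi, e[r])
    meat <- meat + gi %*% t(gi)
  }
  B %*% meat %*% B
}

## brute-force homogeneous sandwich given per-subject covariance blocks
brute_swe_hom <- function(design, Vblocks) {
  B <- solve(crossprod(design$X))
  meat <- matrix(0, design$p, design$p)
  for (i in seq_along(design$subjects)) {
    r <- design$subj_rows[[design$subjects[i]]]
    Xi <- design$X[r, , drop = FALSE]
    meat <- meat + crossprod(Xi, Vblocks[[i]]) %*% Xi
  }
  B %*% meat %*% B
}

balanced_cs <- function(rho = 0.95) cov_structure(alpha = c(A = 1, B = 1),
                                                  rho = rho)
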