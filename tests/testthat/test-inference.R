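test_that("naive df counts pure between-subject columns", {
  d <- build_balanced_design(12, 5)
  nd <- naive_dof(d)
  expect_equal(nd$p_B, 2)          # the two group intercepts
  expect_equal(nd$nu, 10)

  d20 <- one_obs_design(20)
  expect_equal(naive_dof(d20)$nu, 19)
})

test_that("effective df reduces to m - 1 in the sample-mean case", {
  ## deterministic for the homogeneous variant: independent of the data,
  ## matching the Satterthwaite value for a chi-square_(m-1) variance
  ## estimate; the heterogeneous variant plugs in noisy per-subject outer
  ## products and is only required to be positive and finite
  set.seed(21)
  for (m in c(5, 20)) {
    d <- one_obs_design(m)
    fit <- swe_fit(d, rnorm(m), "hom", "S0")
    expect_equal(estimate_dof(fit, 1)$nu, m - 1, tolerance = 1e-9)
    fit_het <- swe_fit(d, rnorm(m), "het", "S0")
    nu_het <- suppressWarnings(estimate_dof(fit_het, 1)$nu)
    expect_true(is.finite(nu_het) && nu_het > 0)
  }
})

test_that("effective df scales with independent replication of the design", {
  base_tab <- data.frame(subject = rep(sprintf("s%02d", 1:20), each = 3),
                         group = "g", visit = rep(c("v1", "v2", "v3"), 20),
                         time = rep(0:2, 20))
  spec <- list(term_intercept(FALSE), term_time_poly(1, FALSE))
  d1 <- build_design(base_tab, spec)
  y1 <- simulate_responses(d1, cov_structure(rho = 0.5), V = 1, seed = 9)
  nu1 <- estimate_dof(swe_fit(d1, y1, "hom", "S0"), c(0, 1))$nu
  expect_true(is.finite(nu1) && nu1 > 0)
  for (r in c(2, 4)) {
    reps <- do.call(rbind, lapply(seq_len(r), function(j) {
      t <- base_tab; t$subject <- paste0(t$subject, "_", j); t
    }))
    dr <- build_design(reps, spec)
    yr <- matrix(do.call(rbind, replicate(r, list(y1))), ncol = 1)
    nur <- estimate_dof(swe_fit(dr, yr, "hom", "S0"), c(0, 1))$nu
    expect_lt(abs(nur / (r * nu1) - 1), 0.05)
  }
})

test_that("effective df differs between variants in general", {
  set.seed(23)
  d <- build_balanced_design(12, 4)
  Y <- simulate_responses(d, balanced_cs(), V = 1, seed = 23)
  C <- resolve_contrast(d, "diff:time1.A-time1.B")
  nu_hom <- estimate_dof(swe_fit(d, Y, "hom", "S3"), C)$nu
  nu_het <- estimate_dof(swe_fit(d, Y, "het", "S3"), C)$nu
  expect_false(isTRUE(all.equal(nu_hom, nu_het)))
})

test_that("t and F inference agree for rank-1 contrasts", {
  set.seed(24)
  d <- build_balanced_design(16, 4)
  Y <- simulate_responses(d, balanced_cs(), V = 25, seed = 24)
  C <- resolve_contrast(d, "diff:time1.A-time1.B")
  fit <- swe_fit(d, Y, "hom", "S3")
  res <- wald_test(fit, C)
  ## F-path p recomputed from the statistic must equal the t-path p
  pF <- stats::pf(res$stat, 1, res$nu, lower.tail = FALSE)
  expect_equal(res$p, pF, tolerance = 1e-10)
  expect_equal(res$stat, res$t^2, tolerance = 1e-12)
})

test_that("a known t statistic gives the textbook p-value", {
  ## t = 2 on 10 df: two-sided p ~= 0.0734
  d <- one_obs_design(11)
  fit <- swe_fit(d, rnorm(11), "hom", "S0")
  ## override: inject beta and covariance so that t = 2 exactly
  fit$beta <- matrix(2)
  fit$S_flat <- matrix(1)
  fit$S <- array(1, c(1, 1, 1))
  res <- wald_test(fit, 1, dof = 10)
  expect_equal(res$t, 2)
  expect_equal(res$p, 2 * stats::pt(-2, 10), tolerance = 1e-12)
  expect_equal(res$p, 0.0734, tolerance = 1e-3)
  ## one-sided halves the two-sided p here
  res_g <- wald_test(fit, 1, dof = 10, alternative = "greater")
  expect_equal(res_g$p, res$p / 2, tolerance = 1e-12)
})

test_that("the F rescaling uses (nu - q + 1) / (nu q)", {
  set.seed(26)
  d <- build_balanced_design(14, 4)
  Y <- simulate_responses(d, balanced_cs(), V = 1, seed = 26)
  C <- rbind(resolve_contrast(d, "diff:time1.A-time1.B"),
             resolve_contrast(d, "diff:time2.A-time2.B"))
  fit <- swe_fit(d, Y, "hom", "S3")
  res <- wald_test(fit, C, dof = 10)
  cb <- C %*% fit$beta
  W <- matrix((C %x% C) %*% fit$S_flat, 2, 2)
  quad <- as.numeric(t(cb) %*% solve(W, cb))
  expect_equal((10 - 2 + 1) / (10 * 2), 0.45)
  expect_equal(res$stat, 0.45 * quad, tolerance = 1e-12)
  expect_equal(res$df2, 9)
})

test_that("the F p-value converges to the chi-square p-value as nu grows", {
  set.seed(27)
  d <- build_balanced_design(12, 5)
  Y <- simulate_responses(d, balanced_cs(0.5), V = 5, seed = 27)
  C <- rbind(resolve_contrast(d, "diff:time1.A-time1.B"),
             resolve_contrast(d, "diff:time2.A-time2.B"))
  fit <- swe_fit(d, Y, "hom", "S0")
  nu <- 1e6
  res <- wald_test(fit, C, dof = nu)
  quad <- res$stat * (nu * 2) / (nu - 2 + 1)
  p_chi <- stats::pchisq(quad, df = 2, lower.tail = FALSE)
  expect_lt(max(abs(res$p - p_chi)), 1e-3)
})

test_that("p-values are monotone in the statistic at fixed df", {
  stats_seq <- seq(0.1, 9, length.out = 20)
  p <- stats::pf(stats_seq, 2, 8, lower.tail = FALSE)
  expect_true(all(diff(p) < 0))
  ## and through the package path: larger |t| -> smaller p
  d <- one_obs_design(12)
  fit <- swe_fit(d, rnorm(12), "hom", "S0")
  fit$S_flat <- matrix(1); fit$S <- array(1, c(1, 1, 1))
  ps <- vapply(c(0.5, 1, 2, 3), function(b) {
    fit$beta <- matrix(b)
    wald_test(fit, 1, dof = 11)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("multiplicity control matches hand-computed masks", {
  expect_equal(multiplicity_control(c(0.001, 0.04, 0.9), "bonferroni", 0.05),
               c(TRUE, FALSE, FALSE))
  expect_equal(multiplicity_control(c(0.01, 0.02, 0.9), "fdr", 0.05),
               c(TRUE, TRUE, FALSE))
  expect_equal(multiplicity_control(rep(1, 5), "fdr", 0.05), rep(FALSE, 5))
  expect_error(multiplicity_control(numeric(0)), "empty")
  ## BH rejections are a superset of Bonferroni rejections
  set.seed(30)
  for (i in 1:10) {
    p <- runif(50)^2
    bh <- multiplicity_control(p, "fdr", 0.05)
    bf <- multiplicity_control(p, "bonferroni", 0.05)
    expect_true(all(bh[bf]))
  }
})

test_that("degenerate contrasts are rejected with informative errors", {
  set.seed(31)
  d <- build_balanced_design(10, 3)
  Y <- simulate_responses(d, balanced_cs(), V = 1, seed = 31)
  fit <- swe_fit(d, Y, "hom", "S3")
  expect_error(wald_test(fit, rep(0, d$p)), "rank 0")
  ## duplicated rows are reduced with a warning
  C <- resolve_contrast(d, "diff:time1.A-time1.B")
  expect_warning(res <- wald_test(fit, rbind(C, C), dof = 8),
                 "linearly dependent")
  expect_equal(res$df1, 1)
})
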