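test_that("residual adjustments apply the documented factors", {
  h <- rep(0.2, 10)
  e <- matrix(1, 10, 1)
  expect_equal(adjust_residuals(e, h, 10, 2, "S0"), e)
  expect_equal(adjust_residuals(e, h, 10, 2, "S1")[1, 1], sqrt(10 / 8),
               tolerance = 1e-9)
  expect_equal(adjust_residuals(matrix(0.6), 0.4, 5, 1, "S3")[1, 1], 1.0)
  expect_equal(adjust_residuals(matrix(0.6), 0.19, 5, 1, "S2")[1, 1],
               0.6 / sqrt(0.81), tolerance = 1e-9)
  expect_equal(adjust_residuals(matrix(0.6), 0.19, 5, 1, "S2")[1, 1],
               0.666667, tolerance = 1e-6)
  expect_error(adjust_residuals(e, c(rep(0.2, 9), 1), 10, 2, "S2"),
               "row\\(s\\) 10")
})

test_that("heterogeneous sandwich matches hand and brute-force oracles", {
  ## two singleton subjects, e = (1, -1): bread 1/2, meat 2
  d2 <- one_obs_design(2)
  S <- swe_heterogeneous(d2, matrix(c(1, -1), 2, 1))
  expect_equal(S[1, 1, 1], 0.5)

  ## zero residuals -> zero covariance
  d <- build_balanced_design(8, 3)
  S0 <- swe_heterogeneous(d, matrix(0, d$n, 2))
  expect_true(all(S0 == 0))

  ## HC0 variance of a mean: S = sum e_i^2 / n^2, via per-subject loop oracle
  set.seed(3)
  dm <- one_obs_design(12)
  e <- fit_ols(dm, rnorm(12))$residuals
  S1 <- swe_heterogeneous(dm, e)[1, 1, 1]
  expect_equal(S1, sum(e^2) / 144, tolerance = 1e-12)
  expect_equal(S1, brute_swe_het(dm, e)[1, 1], tolerance = 1e-12)

  ## general design against the brute-force oracle
  set.seed(4)
  db <- build_balanced_design(10, 4)
  eb <- fit_ols(db, rnorm(db$n))$residuals
  expect_equal(swe_heterogeneous(db, eb)[, , 1], brute_swe_het(db, eb),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("group covariance reproduces hand-computed cases", {
  ## subjects A: (1,1), B: (-1,1) at visits 1,2 -> identity
  tab <- data.frame(subject = rep(c("a", "b"), each = 2), group = "g",
                    visit = rep(c("v1", "v2"), 2), time = rep(0:1, 2))
  d <- design_from_matrix(matrix(0.0 + diag(4)[, 1], 4, 1), tab)
  ## use an explicit design only as a carrier; pass residuals directly
  gc <- estimate_group_covariance(d, matrix(c(1, 1, -1, 1), 4, 1))
  expect_equal(gc$est[["g"]]$V[, , 1], diag(2), ignore_attr = TRUE)
  expect_equal(gc$est[["g"]]$M, matrix(2L, 2, 2), ignore_attr = TRUE)

  ## missing data: A (1,2) at visits 1,2; B (3) at visit 1
  tab2 <- data.frame(subject = c("a", "a", "b"), group = "g",
                     visit = c("v1", "v2", "v1"), time = c(0, 1, 0))
  d2 <- design_from_matrix(matrix(c(1, 0, 1), 3, 1), tab2)
  gc2 <- estimate_group_covariance(d2, matrix(c(1, 2, 3), 3, 1))
  V <- gc2$est[["g"]]$V[, , 1]
  expect_equal(diag(V), c(5, 4), ignore_attr = TRUE)
  expect_equal(gc2$est[["g"]]$rho[1, 2, 1], 1)
  expect_equal(V[1, 2], sqrt(20), tolerance = 1e-12)
  expect_equal(gc2$est[["g"]]$M[1, ], c(2L, 1L), ignore_attr = TRUE)

  ## per-subject groups with complete data: V0g = outer product of residuals
  d3 <- per_subject_groups(simple_long_design(3, 2))
  E <- matrix(rnorm(6), 6, 1)
  gc3 <- estimate_group_covariance(d3, E)
  for (i in seq_along(d3$subjects)) {
    r <- d3$subj_rows[[d3$subjects[i]]]
    expect_equal(gc3$est[[d3$subj_group[i]]]$V[, , 1], tcrossprod(E[r, 1]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("psd_repair clamps negative eigenvalues and is idempotent", {
  V <- matrix(c(1, 2, 2, 1), 2)
  R <- psd_repair(V)
  expect_equal(unclass(R), matrix(1.5, 2, 2), ignore_attr = TRUE)
  I2 <- diag(2)
  expect_equal(unclass(psd_repair(I2)), I2, ignore_attr = TRUE)
  R2 <- psd_repair(R)
  expect_equal(unclass(R2), unclass(R), ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(psd_repair(matrix(c(1, 2, 3, 1), 2)), "symmetric")
})

test_that("homogeneous SwE with per-subject groups equals the heterogeneous
           SwE for every adjustment", {
  set.seed(5)
  d <- simple_long_design(6, 3)
  dg <- per_subject_groups(d)
  Y <- matrix(rnorm(d$n * 3), d$n, 3)
  for (adj in c("S0", "S1", "S2", "S3")) {
    fhom <- swe_fit(dg, Y, "hom", adj)
    fhet <- swe_fit(dg, Y, "het", adj)
    expect_equal(fhom$S, fhet$S, tolerance = 1e-12)
  }
})

test_that("homogeneous SwE matches a brute-force per-subject assembly", {
  set.seed(6)
  d <- build_balanced_design(10, 4)
  Y <- rnorm(d$n)
  fit <- swe_fit(d, Y, "hom", "S0")
  gc <- fit$group_cov
  Vblocks <- lapply(seq_along(d$subjects), function(i) {
    r <- d$subj_rows[[d$subjects[i]]]
    gc$est[[d$subj_group[i]]]$V[d$visit_idx[r], d$visit_idx[r], 1]
  })
  expect_equal(fit$S[, , 1], brute_swe_hom(d, Vblocks), tolerance = 1e-12,
               ignore_attr = TRUE)

  ## zero common covariance -> zero S
  gc0 <- gc
  for (g in names(gc0$est)) gc0$est[[g]]$V[] <- 0
  expect_true(all(swe_homogeneous(d, gc0) == 0))
})

test_that("every returned S is symmetric positive semi-definite", {
  set.seed(8)
  d <- build_balanced_design(12, 5)
  Y <- simulate_responses(d, balanced_cs(), V = 20, seed = 8)
  for (variant in c("het", "hom")) {
    fit <- swe_fit(d, Y, variant, "S3")
    for (v in seq_len(20)) {
      S <- fit$S[, , v]
      expect_lt(max(abs(S - t(S))), 1e-12)
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-10 * max(ev))
    }
  }
})

test_that("S2 equals the textbook HC2 estimator from an independent
           implementation", {
  skip_if_not_installed("sandwich")
  set.seed(14)
  x <- rnorm(15)
  tab <- data.frame(subject = sprintf("s%02d", 1:15), group = "g",
                    visit = "v1", time = 0, x = x)
  d <- build_design(tab, list(term_intercept(FALSE), term_covariate("x")))
  y <- as.numeric(align_scans(d, 1 + 2 * x + rnorm(15)))
  e <- fit_ols(d, y)$residuals
  S <- swe_heterogeneous(d, adjust_residuals(e, d$hat, d$n, d$p, "S2"))[, , 1]
  ref <- sandwich::vcovHC(stats::lm(y ~ d$X - 1), type = "HC2")
  expect_equal(S, ref, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("contrast-wise storage agrees bit-for-bit with the full-S path", {
  set.seed(15)
  d <- build_balanced_design(10, 3)
  Y <- simulate_responses(d, balanced_cs(), V = 7, seed = 15)
  C <- rbind(resolve_contrast(d, "diff:time1.A-time1.B"),
             resolve_contrast(d, "diff:intercept.A-intercept.B"))
  lean <- swe_fit(d, Y, "hom", "S3", contrast = C, return_S = FALSE)
  full <- swe_fit(d, Y, "hom", "S3")
  ref <- (C %x% C) %*% full$S_flat
  expect_identical(matrix(lean$CSC, 4, 7), ref)
})

test_that("the SwE is a consistent variance estimate under simulation", {
  ## mean of the SwE diagonal across replications matches the Monte-Carlo
  ## variance of beta-hat within 3 standard errors
  d <- build_balanced_design(40, 4)
  V <- 800
  Y <- simulate_responses(d, balanced_cs(0.5), V = V, seed = 99)
  fit <- swe_fit(d, Y, "hom", "S3")
  j <- match("time1.A", colnames(d$X))
  mc_var <- var(fit$beta[j, ])
  swe_mean <- mean(fit$S[j, j, ])
  ## SE of the MC variance of a (near) normal mean estimate
  se <- mc_var * sqrt(2 / (V - 1))
  expect_lt(abs(swe_mean - mc_var), 3 * se)
})

test_that("group covariance estimates serialise to CSV", {
  d <- build_balanced_design(8, 3)
  fit <- swe_fit(d, simulate_responses(d, balanced_cs(), V = 1, seed = 2),
                 "hom", "S3")
  dir <- withr::local_tempdir()
  paths <- write_group_cov_csv(fit$group_cov, dir)
  expect_length(paths, 2)
  back <- utils::read.csv(paths[1])
  expect_equal(back$visit, c("v1", "v2", "v3"))
  expect_equal(back$m.v1, rep(4L, 3))
})
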