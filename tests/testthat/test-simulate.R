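test_that("covariance matrices follow the variance and correlation rules", {
  ## gamma = psi = 0: exact compound symmetry
  p1 <- cov_structure(alpha = 1, rho = 0.7)
  V1 <- cov_matrix(p1, c(0, 1, 3))
  expect_equal(diag(V1), rep(1, 3))
  expect_true(all(abs(V1[upper.tri(V1)] - 0.7) < 1e-12))

  ## variance 1 * (1 + 2 * 1.5) = 4
  p2 <- cov_structure(alpha = 1, gamma = 2)
  expect_equal(diag(cov_matrix(p2, c(0, 1.5)))[2], 4)

  ## correlation 1 * (1 - 0.2 * 2) = 0.6
  p3 <- cov_structure(alpha = 1, rho = 1, psi = 0.2)
  V3 <- cov_matrix(p3, c(0, 2))
  expect_equal(V3[1, 2], 0.6)

  expect_error(cov_matrix(cov_structure(alpha = 1, gamma = -0.9), c(0, 2)),
               "non-positive variance")
})

test_that("preset parameter rows build valid covariances without repair", {
  for (dsg in c("balanced", "adni")) {
    times <- if (dsg == "balanced") 0:4 else c(0, 0.5, 1, 1.5, 2, 3)
    for (nm in c("cs", "toeplitz", "het_groups", "het_visits")) {
      params <- longswe:::.preset_cov(nm, dsg)
      for (g in names(params$alpha))
        expect_no_warning(cov_matrix(params, times, g))
    }
  }
})

test_that("balanced designs have the documented structure", {
  d <- build_balanced_design(12, 3)
  expect_equal(d$n, 36L)
  expect_equal(d$p, 6L)
  expect_equal(as.integer(table(d$subj_group)), c(6L, 6L))

  d25 <- build_balanced_design(25, 5)
  expect_equal(as.integer(table(d25$subj_group)), c(13L, 12L))

  ## per-group polynomial columns are mutually orthogonal
  for (g in d$groups) {
    cols <- grep(paste0("\\.", g, "$"), colnames(d$X))
    G <- crossprod(d$X[, cols])
    expect_lt(max(abs(G - diag(diag(G)))), 1e-10)
  }
  expect_error(build_balanced_design(12, 2, degree = 2), "polynomial")
})

test_that("test statistics are invariant to the time-polynomial basis", {
  ## the same column space coded two ways must give identical tests
  d <- build_balanced_design(10, 4)
  tab <- data.frame(subject = d$subject, group = d$group, visit = d$visit,
                    time = d$time)
  raw <- cbind(ifelse(d$group == "A", 1, 0), ifelse(d$group == "B", 1, 0),
               ifelse(d$group == "A", d$time, 0),
               ifelse(d$group == "A", d$time^2, 0),
               ifelse(d$group == "B", d$time, 0),
               ifelse(d$group == "B", d$time^2, 0))
  colnames(raw) <- colnames(d$X)
  d_raw <- design_from_matrix(raw, tab)
  Y <- simulate_responses(d, balanced_cs(0.5), V = 10, seed = 51)
  ## the quadratic-effect contrast spans the same tested subspace
  C1 <- resolve_contrast(d, "diff:time2.A-time2.B")
  f1 <- swe_fit(d, Y, "hom", "S3")
  ## in the raw basis the quadratic difference needs the raw quadratic column
  C2 <- resolve_contrast(d_raw, "diff:time2.A-time2.B")
  f2 <- swe_fit(d_raw, Y, "hom", "S3")
  ## statistics differ column-wise but the joint visit-effect test (all 4
  ## time columns) is basis-invariant
  Cj1 <- diag(d$p)[match(c("time1.A", "time2.A", "time1.B", "time2.B"),
                         colnames(d$X)), ]
  Cj2 <- diag(d$p)[match(c("time1.A", "time2.A", "time1.B", "time2.B"),
                         colnames(raw)), ]
  w1 <- wald_test(f1, Cj1, dof = 100)
  w2 <- wald_test(f2, Cj2, dof = 100)
  expect_equal(w1$stat, w2$stat, tolerance = 1e-8)
})

test_that("the unbalanced three-group emulator matches its count table", {
  b <- build_adni_like_design(seed = 11)
  d <- b$design
  expect_equal(d$m, 817L)
  expect_equal(d$n, 3314L)

  counts <- adni_visit_counts()
  tab <- b$table
  for (g in colnames(counts)) for (r in rownames(counts)) {
    expected <- counts[r, g]
    if (is.na(expected)) expected <- 0L
    got <- sum(tab$group == g & tab$visit == paste0("m", r))
    expect_equal(got, as.integer(expected))
  }

  ## mean scans per subject, as published
  scans <- tapply(tab$subject, tab$group, length) /
    tapply(tab$subject, tab$group, function(s) length(unique(s)))
  expect_equal(as.numeric(round(scans[c("N", "MCI", "AD")], 2)),
               c(4.16, 4.43, 3.14))

  ## 12 design columns: 3 intercepts + 3 cross age + 3 visit + 3 acceleration
  expect_equal(d$p, 12L)
  expect_equal(sum(longswe:::.between_columns(d)), 6)
  expect_equal(naive_dof(d)$nu, 811)

  ## baseline age distributions
  base <- tab[tab$visit == "m0", ]
  mu <- tapply(base$age, base$group, mean)
  expect_equal(as.numeric(mu[c("N", "MCI", "AD")]), c(76.0, 74.8, 75.4),
               tolerance = 0.75)
})

test_that("count tables that exceed baseline are rejected", {
  counts <- adni_visit_counts()
  counts["6", "AD"] <- 500
  expect_error(build_adni_like_design(counts, seed = 1), "exceeds")
})

test_that("halving keeps floor(m_g / 2) subjects per group", {
  b <- build_adni_like_design(seed = 11)
  th <- halve_subjects(b$table, seed = 12)
  sizes <- table(unique(th[, c("subject", "group")])$group)
  expect_equal(unname(sizes[c("N", "MCI", "AD")]), c(114L, 200L, 94L),
               ignore_attr = TRUE)
})

test_that("the generator is reproducible and honours its null settings", {
  d <- build_balanced_design(12, 3)
  p0 <- cov_structure(alpha = c(A = 1, B = 1))
  Y1 <- simulate_responses(d, p0, V = 3, seed = 7)
  Y2 <- simulate_responses(d, p0, V = 3, seed = 7)
  expect_identical(Y1, Y2)

  ## rho = gamma = psi = 0: i.i.d. standard normal
  dbig <- build_balanced_design(1000, 4, degree = 1)
  Yn <- simulate_responses(dbig, p0, V = 3, seed = 8)
  ks <- stats::ks.test(as.numeric(Yn)[1:10000], "pnorm")
  expect_gt(ks$p.value, 0.01)
})

test_that("simulated data reproduce each preset covariance row", {
  m <- 10000
  d <- build_balanced_design(m, 3, degree = 1)
  for (nm in c("cs", "toeplitz", "het_groups", "het_visits")) {
    params <- longswe:::.preset_cov(nm, "balanced")
    Y <- simulate_responses(d, params, V = 1, seed = 60 + match(nm, c("cs",
      "toeplitz", "het_groups", "het_visits")))
    for (g in d$groups) {
      rows <- which(d$group == g)
      M <- matrix(Y[rows, 1], nrow = 3)
      emp <- tcrossprod(M) / ncol(M)       # mean-zero by construction
      theo <- cov_matrix(params, 0:2, g)
      n_g <- ncol(M)
      for (a in 1:3) for (b in a:3) {
        se <- sqrt((theo[a, a] * theo[b, b] + theo[a, b]^2) / n_g)
        expect_lt(abs(emp[a, b] - theo[a, b]), 3.5 * se)
      }
    }
  }
})

test_that("within-subject correlation matches the CS target closely", {
  d <- build_balanced_design(10000, 3, degree = 1)
  Y <- simulate_responses(d, balanced_cs(0.95), V = 1, seed = 23)
  M <- matrix(Y[, 1], nrow = 3)
  cors <- cor(t(M))[upper.tri(diag(3))]
  expect_true(all(abs(cors - 0.95) < 0.02))
})

test_that("the signal option adds a subject-centred time effect", {
  d <- build_balanced_design(8, 3)
  p0 <- cov_structure(alpha = c(A = 1, B = 1))
  Y0 <- simulate_responses(d, p0, effect_size = 0, V = 1, seed = 3)
  Y1 <- simulate_responses(d, p0, effect_size = 2, V = 1, seed = 3)
  ct <- d$time - stats::ave(d$time, d$subject)
  expect_equal(Y1 - Y0, matrix(2 * ct, ncol = 1), tolerance = 1e-12)
  ## per-group effects
  Yg <- simulate_responses(d, p0, effect_size = c(A = 1, B = 0), V = 1,
                           seed = 3)
  diffs <- (Yg - Y0)[d$group == "B", 1]
  expect_true(all(diffs == 0))
})
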