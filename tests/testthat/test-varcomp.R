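test_that("balanced designs recover the closed-form EMS coefficients", {
  d <- simulate_sib_design(4, 2, 3, h2 = 0.3, seed = 1)
  tab <- nested_anova(d)
  expect_equal(tab$k1, 3)
  expect_equal(tab$k2, 3)
  expect_equal(tab$k3, 6)
  expect_equal(tab$df_s + tab$df_d + tab$df_w, nrow(d) - 1L)
})

test_that("sums of squares match the definitional double loop", {
  set.seed(4)
  d <- simulate_sib_design(4, 2, 3, h2 = 0.4, seed = 4)
  # unbalance it: drop some progeny
  d <- d[-c(2, 9, 17), ]
  tab <- nested_anova(d)
  o <- nested_ss_oracle(d)
  expect_equal(tab$ss_s, o$ss_s, tolerance = 1e-10)
  expect_equal(tab$ss_d, o$ss_d, tolerance = 1e-10)
  expect_equal(tab$ss_w, o$ss_w, tolerance = 1e-10)
  # partition identity
  expect_equal(tab$ss_s + tab$ss_d + tab$ss_w,
               sum((d$value - mean(d$value))^2), tolerance = 1e-9)
})

test_that("degenerate designs raise informative errors", {
  d <- data.frame(sire = rep(c("S1", "S2"), each = 4),
                  dam = rep(c("D1", "D2", "D3", "D4"), each = 2),
                  value = rep(5, 8))
  expect_error(nested_anova(d), "TOTAL_VARIANCE_ZERO")
  d$value <- rnorm(8)
  d$dam[1] <- "D3"  # dam crossing sires
  expect_error(nested_anova(d), "nested")
  # every dam a single progeny: no within-dam stratum
  d2 <- data.frame(sire = c("S1", "S1", "S2", "S2"),
                   dam = c("D1", "D2", "D3", "D4"), value = rnorm(4))
  expect_error(nested_anova(d2), "within-dam")
})

test_that("input order never changes the analysis", {
  d <- simulate_sib_design(5, 3, 4, h2 = 0.25, seed = 8)
  t1 <- nested_anova(d)
  set.seed(1)
  t2 <- nested_anova(d[sample.int(nrow(d)), ])
  for (f in c("ss_s", "ss_d", "ss_w", "k1", "k2", "k3", "sigma2_s",
              "sigma2_d", "sigma2_w")) {
    expect_equal(t1[[f]], t2[[f]], tolerance = 1e-12)
  }
})

test_that("heritability arithmetic follows the component formulas", {
  tab <- structure(list(sigma2_s = 0.075, sigma2_d = 0.075, sigma2_w = 0.85),
                   class = "anova_table")
  expect_equal(h2_from_anova(tab, "SIRE_DAM")$h2_raw, 0.30)
  expect_equal(h2_from_anova(tab, "SIRE")$h2_raw, 0.30)
  zero <- structure(list(sigma2_s = 0, sigma2_d = 0, sigma2_w = 1),
                    class = "anova_table")
  for (cm in c("SIRE", "DAM", "SIRE_DAM")) {
    expect_equal(h2_from_anova(zero, cm)$h2_raw, 0)
  }
  # clamping
  big <- structure(list(sigma2_s = 0.5, sigma2_d = 0.1, sigma2_w = 0.4),
                   class = "anova_table")
  expect_gt(h2_from_anova(big, "SIRE")$h2_raw, 1)
  expect_equal(h2_from_anova(big, "SIRE")$h2_clamped, 1)
})

test_that("sire and dam estimates agree in expectation without maternal effects", {
  set.seed(12)
  diffs <- replicate(200, {
    seed <- sample.int(1e6, 1)
    d <- simulate_sib_design(15, 3, 4, h2 = 0.3, seed = seed)
    tab <- nested_anova(d)
    h2_from_anova(tab, "SIRE")$h2_raw - h2_from_anova(tab, "DAM")$h2_raw
  })
  expect_gt(t.test(diffs)$p.value, 0.01)
})

test_that("design matrices follow the reference-level and farm rules", {
  sim <- simulate_flock(sim_params(n_founder_sires = 3, n_founder_dams = 6,
                                   n_generations = 2, n_farms = 1, seed = 21))
  ds <- sim$dataset
  # single year of W12M records, one farm: mean + sex contrast only
  suppressMessages(dm <- build_design_matrices(ds, "BWT", fixed = "sex"))
  expect_equal(ncol(dm$X), 2)
  expect_equal(qr(dm$X)$rank, 2)

  sim2 <- simulate_flock(sim_params(n_founder_sires = 3, n_founder_dams = 6,
                                    n_generations = 2, n_farms = 2, seed = 21))
  suppressMessages(dm2 <- build_design_matrices(sim2$dataset, "BWT",
                                                fixed = "sex"))
  expect_true(any(grepl("farm", colnames(dm2$X))))
  expect_error(build_design_matrices(ds, "GFY"), "no records")
})

test_that("fixed-effect solutions recover the simulated sex difference", {
  sim <- simulate_flock(sim_params(n_founder_sires = 10, n_founder_dams = 80,
                                   n_generations = 2, sex_effect = 2,
                                   n_farms = 1, seed = 33))
  dm <- suppressMessages(
    build_design_matrices(sim$dataset, "W12M", fixed = "sex"))
  bhat <- qr.solve(dm$X, dm$y)
  sexcol <- grep("MALE", names(bhat))
  expect_equal(unname(bhat[sexcol]), 2, tolerance = 0.8)  # Monte-Carlo slack
})

test_that("EM-REML matches an independent grid search in a grouped design", {
  set.seed(6)
  q <- 15; nrep <- 4; n <- q * nrep
  g <- rep(seq_len(q), each = nrep)
  y <- 5 + rnorm(q, 0, 1.2)[g] + rnorm(n, 0, 1)
  X <- matrix(1, n, 1)
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = g, x = 1, dims = c(n, q),
                            dimnames = list(NULL, paste0("U", seq_len(q))))
  fit <- reml_animal(y, X, Z, Matrix::Diagonal(q), tol = 1e-10, maxit = 5000)
  # dense grid over the variance ratio, profiling the REML likelihood
  grid <- expand.grid(s2u = seq(0.05, 4, by = 0.01),
                      s2e = fit$sigma2_e)
  ll <- mapply(function(a, b) reml_loglik_oracle(y, X, Z, diag(q), a, b),
               grid$s2u, grid$s2e)
  expect_equal(grid$s2u[which.max(ll)], fit$sigma2_u, tolerance = 2e-2)
  # and the likelihood never decreased relative to the start point
  expect_gte(reml_loglik_oracle(y, X, Z, diag(q), fit$sigma2_u, fit$sigma2_e),
             reml_loglik_oracle(y, X, Z, diag(q), var(y) / 2, var(y) / 2))
})

test_that("a near-perfect fixed-effect fit drives the additive variance to zero", {
  set.seed(9)
  n <- 30
  sex <- rep(c("M", "F"), n / 2)
  X <- cbind(1, sex == "M")
  y <- as.numeric(X %*% c(10, 3)) + rnorm(n, 0, 1e-3)
  g <- rep(seq_len(n / 3), each = 3)  # replicated units, no unit effect
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = g, x = 1,
                            dims = c(n, n / 3),
                            dimnames = list(NULL, paste0("A", seq_len(n / 3))))
  fit <- reml_animal(y, X, Z, Matrix::Diagonal(n / 3), maxit = 2000)
  expect_lt(fit$sigma2_u, 1e-8)
  expect_lt(fit$h2, 0.01)
})

test_that("the REML wrapper agrees with lme4 on a sire-structured flock", {
  skip_if_not_installed("lme4")
  sim <- simulate_flock(sim_params(n_founder_sires = 8, n_founder_dams = 60,
                                   n_generations = 2, n_farms = 1, seed = 17))
  ds <- sim$dataset
  dm <- suppressMessages(build_design_matrices(ds, "W12M", fixed = "sex",
                                               random_unit = "SIRE"))
  Ai <- Matrix::Diagonal(length(dm$unit_ids))
  fit <- reml_animal(dm$y, dm$X, dm$Z, Ai, tol = 1e-10, maxit = 5000)
  df <- data.frame(y = dm$y, sex = dm$records$sex, sire = dm$records$sire)
  lf <- lme4::lmer(y ~ sex + (1 | sire), data = df, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))$vcov
  expect_equal(fit$sigma2_u, vc[1], tolerance = 1e-4)
  expect_equal(fit$sigma2_e, vc[2], tolerance = 1e-4)
})
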