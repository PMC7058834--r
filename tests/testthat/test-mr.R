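test_that("Wald ratios follow the delta-method formulas", {
  r <- wald_ratio(beta_exp = 0.5, beta_out = 0, se_out = 0.01)
  expect_equal(r$estimate, 0)
  expect_equal(r$se, 0.02)
  r <- wald_ratio(beta_exp = 0.2, se_exp = 0.02, beta_out = 0.1,
                  se_out = 0.02)
  expect_equal(r$estimate, 0.5)
  expect_equal(r$se, 0.1)
  r2 <- wald_ratio(beta_exp = 0.2, se_exp = 0.02, beta_out = 0.1,
                   se_out = 0.02, se_order = "second")
  expect_equal(r2$se, sqrt(0.02^2 / 0.04 + 0.01 * 4e-4 / 0.0016))
  expect_error(wald_ratio(beta_exp = 0, beta_out = 0.1, se_out = 0.02),
               "weak instrument")
})

test_that("second-order Wald SE matches a Monte-Carlo ratio-SD oracle", {
  set.seed(42)
  n <- 1e6
  bx <- rnorm(n, 0.5, 0.05)
  by <- rnorm(n, 0.1, 0.02)
  mc_sd <- sd(by / bx)
  delta <- wald_ratio(beta_exp = 0.5, se_exp = 0.05, beta_out = 0.1,
                      se_out = 0.02, se_order = "second")$se
  expect_lt(abs(delta - mc_sd) / mc_sd, 0.05)
})

test_that("fixed-effects IVW pools ratios by inverse variance", {
  r <- wald_ratio(beta_exp = c(1, 1), beta_out = c(0.5, 0.5),
                  se_out = c(0.1, 0.1))
  f <- ivw_fixed(r)
  expect_equal(f$estimate, 0.5)
  expect_equal(f$se, 0.1 / sqrt(2))
  # hand-weighted mean: weights 100 and 25
  r <- data.frame(estimate = c(0.2, 0.6), se = c(0.1, 0.2))
  f <- ivw_fixed(r)
  expect_equal(f$estimate, 0.28, tolerance = 1e-12)
  expect_equal(f$se, 1 / sqrt(125), tolerance = 1e-12)
  expect_equal(f$method, "ivw")
  # a single ratio passes through unchanged, tagged as a Wald ratio
  f1 <- ivw_fixed(data.frame(estimate = -0.101, se = 0.010))
  expect_equal(f1$method, "wald")
  expect_equal(f1$estimate, -0.101)
  expect_equal(f1$se, 0.010)
  expect_error(ivw_fixed(data.frame(estimate = numeric(), se = numeric())),
               "no ratio")
})

test_that("MR-Egger recovers exact linear relationships", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h <- toy_harmonized(bx, 0.01, 1.0 * bx, c(0.01, 0.02, 0.01, 0.02))
  f <- mr_egger(h)
  expect_equal(f$estimate, 1.0, tolerance = 1e-9)
  expect_equal(f$intercept, 0, tolerance = 1e-9)
  h <- toy_harmonized(bx, 0.01, 0.05 + 1.0 * bx, c(0.01, 0.02, 0.01, 0.02))
  f <- mr_egger(h)
  expect_equal(f$estimate, 1.0, tolerance = 1e-9)
  expect_equal(f$intercept, 0.05, tolerance = 1e-9)
  expect_error(mr_egger(toy_harmonized(1:2 / 10, 0.01, 1:2 / 10, 0.01)),
               "at least 3")
  expect_error(mr_egger(toy_harmonized(rep(0.2, 4), 0.01, 1:4 / 10, 0.01)),
               "degenerate")
})

test_that("MR-Egger equals the brute-force weighted normal equations", {
  set.seed(7)
  bx <- c(0.12, 0.25, 0.31, 0.18, 0.40, 0.22)
  by <- 0.04 + 0.8 * bx + rnorm(6, 0, 0.02)
  sy <- c(0.01, 0.03, 0.02, 0.015, 0.025, 0.02)
  h <- toy_harmonized(bx, 0.01, by, sy)
  f <- mr_egger(h)
  # independent route: explicit matrix solve with the same SE convention
  X <- cbind(1, bx)
  W <- diag(1 / sy^2)
  A <- solve(t(X) %*% W %*% X)
  coefs <- unname(drop(A %*% t(X) %*% W %*% by))
  resid <- by - drop(X %*% coefs)
  sigma2 <- sum(resid^2 / sy^2) / (6 - 2)
  ses <- unname(sqrt(diag(A) * max(1, sigma2)))
  expect_equal(f$intercept, coefs[1], tolerance = 1e-9)
  expect_equal(f$estimate, coefs[2], tolerance = 1e-9)
  expect_equal(f$intercept_se, ses[1], tolerance = 1e-9)
  expect_equal(f$se, ses[2], tolerance = 1e-9)
  expect_equal(f$q_stat, sum(resid^2 / sy^2), tolerance = 1e-9)
})

test_that("weighted median interpolates the cumulative-weight midpoints", {
  r <- data.frame(estimate = rep(0.3, 3), se = c(0.1, 0.2, 0.3))
  expect_equal(weighted_median(r, n_boot = 50, seed = 1)$estimate, 0.3)
  r <- data.frame(estimate = c(0.1, 0.4, 0.9), se = 1)
  expect_equal(weighted_median(r, n_boot = 50, seed = 1)$estimate, 0.4)
  # unequal weights: brute-force evaluation of the interpolation formula
  est <- c(0.10, 0.25, 0.40, 0.55, 0.90)
  se <- c(0.10, 0.05, 0.20, 0.08, 0.30)
  w <- (1 / se^2) / sum(1 / se^2)
  S <- cumsum(w) - w / 2
  j <- max(which(S < 0.5))
  manual <- est[j] + (est[j + 1] - est[j]) * (0.5 - S[j]) / (S[j + 1] - S[j])
  f <- weighted_median(data.frame(estimate = est, se = se),
                       n_boot = 50, seed = 1)
  expect_equal(f$estimate, manual, tolerance = 1e-12)
  expect_error(weighted_median(data.frame(estimate = 1:2, se = 1)),
               "at least 3")
})

test_that("weighted-median bootstrap SE is seed-stable at n_boot = 5000", {
  r <- data.frame(estimate = c(0.1, 0.3, 0.35, 0.5, 0.7),
                  se = c(0.1, 0.05, 0.08, 0.1, 0.2))
  s1 <- weighted_median(r, n_boot = 5000, seed = 1)$se
  s2 <- weighted_median(r, n_boot = 5000, seed = 99)$se
  expect_lt(abs(s1 - s2) / s1, 0.02)
  # seeding contract: same seed, same result
  expect_identical(s1, weighted_median(r, n_boot = 5000, seed = 1)$se)
})

test_that("correlated-instrument GLS reduces to IVW under no correlation", {
  bx <- c(0.2, 0.3, 0.4)
  by <- c(0.05, 0.09, 0.11)
  sy <- c(0.01, 0.02, 0.015)
  h <- toy_harmonized(bx, 0.01, by, sy)
  ld <- ld_matrix(h$snp, diag(3))
  f <- ivw_correlated(h, ld)
  # origin-forced weighted regression with weights 1/se_out^2
  wfit <- lm(by ~ bx - 1, weights = 1 / sy^2)
  expect_equal(f$estimate, unname(coef(wfit)), tolerance = 1e-9)
  expect_equal(f$se, sqrt(1 / sum(bx^2 / sy^2)), tolerance = 1e-12)
  # two uncorrelated SNPs equal the IVW of the two Wald ratios
  h2 <- toy_harmonized(bx[1:2], 0.01, by[1:2], sy[1:2])
  f2 <- ivw_correlated(h2, ld_matrix(h2$snp, diag(2)))
  ref <- ivw_fixed(ratio_estimates(h2))
  expect_equal(f2$estimate, ref$estimate, tolerance = 1e-12)
  expect_equal(f2$se, ref$se, tolerance = 1e-12)
})

test_that("correlated-instrument GLS matches an explicit matrix inversion", {
  bx <- c(0.2, 0.3, 0.4)
  by <- c(0.05, 0.09, 0.11)
  sy <- c(0.01, 0.02, 0.015)
  rho <- 0.5^abs(outer(1:3, 1:3, `-`))
  h <- toy_harmonized(bx, 0.01, by, sy)
  f <- ivw_correlated(h, ld_matrix(h$snp, rho))
  omega <- outer(sy, sy) * rho
  oi <- solve(omega)
  est <- drop(t(bx) %*% oi %*% by) / drop(t(bx) %*% oi %*% bx)
  se <- sqrt(1 / drop(t(bx) %*% oi %*% bx))
  expect_equal(f$estimate, est, tolerance = 1e-9)
  expect_equal(f$se, se, tolerance = 1e-9)
})

test_that("GLS prunes rho^2 >= 0.8 pairs by the weaker exposure p-value", {
  bx <- c(0.2, 0.35, 0.4)
  sx <- c(0.1, 0.05, 0.01)   # rs1 has the weakest exposure association
  rho <- diag(3)
  rho[1, 2] <- rho[2, 1] <- 0.95
  h <- toy_harmonized(bx, sx, c(0.05, 0.09, 0.11), 0.01)
  f <- ivw_correlated(h, ld_matrix(h$snp, rho))
  expect_equal(f$pruned, "rs1")
  expect_equal(f$nsnp, 2L)
})

test_that("estimators are scale- and sign-equivariant", {
  set.seed(11)
  bx <- runif(6, 0.1, 0.5)
  by <- 0.4 * bx + rnorm(6, 0, 0.01)
  sx <- runif(6, 0.01, 0.03)
  sy <- runif(6, 0.01, 0.03)
  h <- toy_harmonized(bx, sx, by, sy)
  cc <- 3.7
  hc <- toy_harmonized(bx, sx, cc * by, cc * sy)
  for (m in c("ivw", "egger", "weighted_median")) {
    f <- mr(h, m, seed = 5)
    fc <- mr(hc, m, seed = 5)
    expect_equal(fc$estimate, cc * f$estimate, tolerance = 1e-9)
    expect_equal(fc$se, cc * f$se, tolerance = 1e-9)
  }
  # negating one SNP's exposure and outcome effects (allele relabel)
  flip <- c(-1, rep(1, 5))
  hf <- toy_harmonized(flip * bx, sx, flip * by, sy)
  for (m in c("ivw", "egger", "weighted_median")) {
    expect_equal(mr(hf, m, seed = 5)$estimate, mr(h, m, seed = 5)$estimate,
                 tolerance = 1e-9)
  }
  fg <- ivw_correlated(hf, ld_matrix(hf$snp, diag(6)))
  expect_equal(fg$estimate, ivw_correlated(h, ld_matrix(h$snp, diag(6)))$estimate,
               tolerance = 1e-9)
})

test_that("the weighted median lies within the ratio range", {
  set.seed(13)
  for (i in 1:20) {
    L <- sample(3:8, 1)
    r <- data.frame(estimate = rnorm(L), se = runif(L, 0.05, 0.3))
    f <- weighted_median(r, n_boot = 20, seed = i)
    expect_gte(f$estimate, min(r$estimate))
    expect_lte(f$estimate, max(r$estimate))
  }
})

test_that("Egger adjusts directional pleiotropy where IVW is biased", {
  set.seed(19)
  theta <- 0.1
  L <- 30
  n_rep <- 100
  ivw_est <- egger_est <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    bx0 <- runif(L, 0.1, 0.3)
    alpha <- rnorm(L, 0.02, 0.005)      # directional, InSIDE satisfied
    bx <- rnorm(L, bx0, 0.005)
    by <- rnorm(L, theta * bx0 + alpha, 0.01)
    h <- toy_harmonized(bx, 0.005, by, 0.01)
    ivw_est[i] <- mr(h, "ivw")$estimate
    egger_est[i] <- mr(h, "egger")$estimate
  }
  # IVW is pulled in the pleiotropy direction; the Egger slope is not
  expect_gt(mean(ivw_est) - theta, 3 * sd(ivw_est) / sqrt(n_rep))
  expect_lt(abs(mean(egger_est) - theta), 3 * sd(egger_est) / sqrt(n_rep))

  # balanced pleiotropy leaves IVW unbiased
  for (i in seq_len(n_rep)) {
    bx0 <- runif(L, 0.1, 0.3)
    alpha <- rnorm(L, 0, 0.02)
    bx <- rnorm(L, bx0, 0.005)
    by <- rnorm(L, theta * bx0 + alpha, 0.01)
    ivw_est[i] <- mr(toy_harmonized(bx, 0.005, by, 0.01), "ivw")$estimate
  }
  expect_lt(abs(mean(ivw_est) - theta), 3 * sd(ivw_est) / sqrt(n_rep))
})

test_that("mr_fit methods expose coefficients, intervals and residuals", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h <- toy_harmonized(bx, 0.01, 0.05 + bx, 0.01)
  f <- mr(h, "egger")
  expect_named(coef(f), c("intercept", "slope"))
  ci <- confint(f)
  expect_lt(ci[1], f$estimate)
  expect_gt(ci[2], f$estimate)
  expect_equal(residuals(f), rep(0, 4), tolerance = 1e-9)
  expect_output(print(summary(f)), "Heterogeneity")
  tab <- mr_results_table(list(f), exposure = "cpg1", outcome = "fev1")
  expect_equal(tab$method, "egger")
  expect_equal(tab$nsnp, 4L)
})
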