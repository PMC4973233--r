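test_that("Wald ratio and delta-method standard errors", {
  inst <- make_instruments(0.20, 0.05, 0.10, 0.02)
  w <- wald_ratio(inst)
  expect_equal(w$theta, 0.5)
  expect_equal(w$se, 0.1)
  expect_equal(wald_ratio(make_instruments(0.2, 0.01, 0, 0.02))$theta, 0)
  expect_error(ivw_estimate(make_instruments(0, 0.01, 0.1, 0.02)),
               "undefined ratio")

  # second-order SE against a Monte-Carlo sd of the ratio
  inst2 <- make_instruments(0.20, 0.02, 0.10, 0.02)
  se2 <- wald_ratio(inst2, delta_order = 2)$se
  set.seed(314)
  draws <- rnorm(1e6, 0.10, 0.02) / rnorm(1e6, 0.20, 0.02)
  # a second-order expansion: agreement to a few percent, not exactly
  expect_equal(se2, sd(draws), tolerance = 0.05)
  expect_gt(se2, wald_ratio(inst2, delta_order = 1)$se)
})

test_that("IVW equals the closed-form weighted mean and the WLS-through-origin fit", {
  single <- make_instruments(0.2, 0.01, 0.1, 0.02)
  expect_equal(ivw_estimate(single)$theta, wald_ratio(single)$theta)
  expect_equal(ivw_estimate(single)$se, wald_ratio(single)$se)

  eq <- make_instruments(c(0.1, 0.1), c(0.01, 0.01),
                         c(0.02, 0.04), c(0.01, 0.01))
  expect_equal(ivw_estimate(eq)$theta, 0.3)  # equal weights: plain mean

  inst <- random_instruments(10, seed = 21)
  est <- ivw_estimate(inst)
  wt <- inst$beta_gp^2 / inst$se_gd^2
  ratio <- inst$beta_gd / inst$beta_gp
  expect_equal(est$theta, sum(wt * ratio) / sum(wt), tolerance = 1e-10)
  expect_equal(est$se, 1 / sqrt(sum(wt)), tolerance = 1e-10)
  fit <- lm(beta_gd ~ 0 + beta_gp, data = inst, weights = 1 / inst$se_gd^2)
  expect_equal(est$theta, unname(coef(fit)), tolerance = 1e-10)
})

test_that("profile-likelihood estimate matches a grid-search oracle", {
  # oracle: exhaustive theta grid with the per-SNP nuisance effect
  # maximized in closed form inside each normal pair
  grid_oracle <- function(b, lo = -2, hi = 2, step = 1e-4) {
    thetas <- seq(lo, hi, by = step)
    ll <- vapply(thetas, function(th) {
      xi <- (b$beta_gp / b$se_gp^2 + th * b$beta_gd / b$se_gd^2) /
        (1 / b$se_gp^2 + th^2 / b$se_gd^2)
      sum(-0.5 * ((b$beta_gp - xi)^2 / b$se_gp^2 +
                    (b$beta_gd - th * xi)^2 / b$se_gd^2))
    }, numeric(1))
    thetas[which.max(ll)]
  }
  toy <- make_instruments(c(0.05, 0.08), c(0.01, 0.015),
                          c(0.012, 0.031), c(0.02, 0.025))
  expect_lt(abs(likelihood_estimate(toy)$theta - grid_oracle(toy)), 1e-4)

  toy2 <- make_instruments(c(0.03, 0.06, 0.02), c(0.008, 0.01, 0.005),
                           c(-0.01, 0.02, 0.004), c(0.015, 0.02, 0.01))
  expect_lt(abs(likelihood_estimate(toy2)$theta - grid_oracle(toy2)), 1e-4)
})

test_that("likelihood collapses to IVW without exposure measurement error", {
  inst <- random_instruments(20, seed = 31)
  inst$se_gp <- 1e-8
  expect_equal(likelihood_estimate(inst)$theta, ivw_estimate(inst)$theta,
               tolerance = 1e-4)
})

test_that("profile and Wald intervals behave and agree in the precise limit", {
  inst <- random_instruments(30, seed = 41, theta = 0.25)
  prof <- likelihood_estimate(inst, ci_method = "profile")
  wald <- likelihood_estimate(inst, ci_method = "wald")
  expect_equal(prof$theta, wald$theta)
  expect_true(prof$ci_low < prof$theta && prof$theta < prof$ci_high)

  # high precision: profile quadratic, the two intervals coincide
  hp <- make_instruments(rep(0.05, 8), rep(1e-5, 8),
                         0.05 * 0.3 + c(-3, -2, -1, 0, 0, 1, 2, 3) * 1e-5,
                         rep(1e-4, 8))
  p2 <- likelihood_estimate(hp, ci_method = "profile")
  w2 <- likelihood_estimate(hp, ci_method = "wald")
  expect_equal(p2$ci_low, w2$ci_low, tolerance = 1e-3)
  expect_equal(p2$ci_high, w2$ci_high, tolerance = 1e-3)
})

test_that("weighted median interpolates the weighted ratio distribution", {
  # symmetric: ratios {0.4, 0.5, 0.6}, weights {1/4, 1/2, 1/4}
  inst <- make_instruments(rep(0.1, 3), rep(0.01, 3),
                           c(0.04, 0.05, 0.06),
                           0.1 / sqrt(c(4, 8, 4) / 0.01))
  wm <- weighted_median_estimate(inst, n_boot = 50, seed = 1)
  expect_equal(wm$theta, 0.5, tolerance = 1e-10)

  # degenerate: all ratios equal, tiny SEs -> estimate c, se ~ 0
  inst2 <- make_instruments(rep(0.1, 4), rep(1e-9, 4), rep(0.07, 4),
                            rep(1e-8, 4))
  wm2 <- weighted_median_estimate(inst2, n_boot = 200, seed = 2)
  expect_equal(wm2$theta, 0.7, tolerance = 1e-6)
  expect_lt(wm2$se, 1e-5)

  # J = 7 random set vs a weighted-CDF grid oracle
  inst3 <- random_instruments(7, seed = 51)
  ratio <- inst3$beta_gd / inst3$beta_gp
  wt <- inst3$beta_gp^2 / inst3$se_gd^2
  o <- order(ratio)
  r <- ratio[o]
  p <- cumsum(wt[o] / sum(wt)) - (wt[o] / sum(wt)) / 2
  grid <- seq(min(r), max(r), length.out = 1e6)
  pg <- approx(r, p, xout = grid, rule = 2)$y
  oracle <- grid[which.min(abs(pg - 0.5))]
  wm3 <- weighted_median_estimate(inst3, n_boot = 50, seed = 3)
  expect_lt(abs(wm3$theta - oracle), 1e-4)
})

test_that("weighted median bootstrap is seeded and reproducible", {
  inst <- random_instruments(15, seed = 61)
  a <- weighted_median_estimate(inst, n_boot = 300, seed = 77)
  b <- weighted_median_estimate(inst, n_boot = 300, seed = 77)
  expect_identical(a$se, b$se)
  expect_error(weighted_median_estimate(inst, n_boot = 300), "seed")
})

test_that("Egger regression matches the weighted normal-equations solve", {
  # exact line: intercept and slope recovered with zero residual
  bgp <- c(0.02, 0.03, 0.05, 0.08)
  exact <- make_instruments(bgp, rep(0.003, 4), 0.05 + 1.2 * bgp,
                            rep(0.02, 4))
  eg <- egger_regression(exact)
  expect_equal(eg$slope$theta, 1.2, tolerance = 1e-10)
  expect_equal(eg$intercept$value, 0.05, tolerance = 1e-10)

  # no-pleiotropy null: proportional effects give a zero intercept
  prop <- make_instruments(bgp, rep(0.003, 4), 0.3 * bgp, rep(0.02, 4))
  expect_equal(egger_regression(prop)$intercept$value, 0, tolerance = 1e-12)

  inst <- random_instruments(20, seed = 71)
  eg2 <- egger_regression(inst)
  X <- cbind(1, inst$beta_gp)
  W <- diag(1 / inst$se_gd^2)
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% inst$beta_gd)
  expect_equal(eg2$intercept$value, beta[1], tolerance = 1e-8)
  expect_equal(eg2$slope$theta, beta[2], tolerance = 1e-8)

  flat <- make_instruments(rep(0.02, 5), rep(0.003, 5), rnorm(5, 0, 0.01),
                           rep(0.02, 5))
  expect_error(egger_regression(flat), "collinear")
})

test_that("Egger intercept p-values are uniform under the no-pleiotropy null", {
  set.seed(811)
  pvals <- replicate(500, {
    j <- 40
    bgp <- 0.01 + abs(rnorm(j, 0.02, 0.01))
    se_gd <- runif(j, 0.01, 0.03)
    inst <- make_instruments(bgp, rep(0.002, j),
                             0.2 * bgp + rnorm(j, 0, se_gd), se_gd)
    egger_regression(inst)$intercept$pvalue
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("heterogeneity statistics: Q, df, p, and floored I-squared", {
  same <- make_instruments(rep(0.1, 5), rep(0.01, 5), rep(0.03, 5),
                           rep(0.02, 5))
  h <- snp_heterogeneity(same)
  expect_equal(h$q, 0)
  expect_equal(h$i_squared, 0)
  expect_equal(h$df, 4L)

  # two SNPs constructed so Q equals the 5% chi-square critical value
  q_target <- qchisq(0.95, 1)
  se1 <- 0.1; se2 <- 0.15
  delta <- sqrt(q_target * (se1^2 + se2^2))
  inst <- make_instruments(c(1, 1), c(1e-8, 1e-8), c(0, delta),
                           c(se1, se2))
  h2 <- snp_heterogeneity(inst)
  expect_equal(h2$q, q_target, tolerance = 1e-10)
  expect_equal(h2$pvalue, 0.05, tolerance = 1e-10)

  # permutation invariance
  inst3 <- random_instruments(12, seed = 81)
  h3 <- snp_heterogeneity(inst3)
  h3p <- snp_heterogeneity(inst3[sample(12), ])
  expect_equal(h3$q, h3p$q, tolerance = 1e-12)
})

test_that("stratum heterogeneity matches the two-sample z identity and residual Q", {
  est <- rbind(causal_estimate("likelihood", 0.2, 0.1, 10L),
               causal_estimate("likelihood", 0.2, 0.1, 10L))
  h0 <- strata_heterogeneity(est)
  expect_equal(h0$q, 0)
  expect_equal(h0$pvalue, 1)

  se <- c(0.1, 0.2)
  d <- 1.96 * sqrt(sum(se^2))
  est2 <- rbind(causal_estimate("likelihood", 0, se[1], 5L),
                causal_estimate("likelihood", d, se[2], 5L))
  expect_equal(strata_heterogeneity(est2)$pvalue, 0.05, tolerance = 1e-3)

  # three strata vs the residual Q of the precision-weighted mean
  th <- c(0.1, 0.35, -0.2); s <- c(0.08, 0.12, 0.2)
  est3 <- do.call(rbind, lapply(1:3, function(i) {
    causal_estimate("likelihood", th[i], s[i], 5L)
  }))
  w <- 1 / s^2
  mu <- sum(w * th) / sum(w)
  expect_equal(strata_heterogeneity(est3)$q, sum(w * (th - mu)^2),
               tolerance = 1e-12)
})

test_that("estimators are scale-equivariant in the exposure units", {
  inst <- random_instruments(25, seed = 91, theta = 0.3)
  c0 <- 4.65
  scaled <- inst
  scaled$beta_gp <- inst$beta_gp * c0
  scaled$se_gp <- inst$se_gp * c0
  expect_equal(ivw_estimate(scaled)$theta, ivw_estimate(inst)$theta / c0,
               tolerance = 1e-10)
  expect_equal(likelihood_estimate(scaled)$theta,
               likelihood_estimate(inst)$theta / c0, tolerance = 1e-6)
  expect_equal(egger_regression(scaled)$slope$theta,
               egger_regression(inst)$slope$theta / c0, tolerance = 1e-10)
  expect_equal(weighted_median_estimate(scaled, 100, seed = 8)$theta,
               weighted_median_estimate(inst, 100, seed = 8)$theta * (1 / c0),
               tolerance = 1e-10)
})
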