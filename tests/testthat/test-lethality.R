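test_that("joint damage pmf: normalisation, marginals and guards", {
  p0 <- lethality_params(0, 0.5, 0)
  expect_equal(lethality_joint_pmf(p0, 0L, 0L, 0L), 1)
  par <- lethality_params(3.5, 0.1, 8.9)
  grid <- expand.grid(m = 0:40, p = 0:60)
  tot <- 0
  for (i in seq_len(nrow(grid))) {
    m <- grid$m[i]
    tot <- tot + sum(lethality_joint_pmf(par, rep(m, m + 1L), 0:m,
                                         rep(grid$p[i], m + 1L)))
  }
  expect_equal(tot, 1, tolerance = 1e-9)
  # marginal over q and p recovers Poisson(lambda)
  m_marg <- vapply(0:15, function(m)
    sum(lethality_joint_pmf(par, rep(m, m + 1L), 0:m, 0L)) /
      dpois(0L, par$gamma), numeric(1))
  expect_equal(m_marg, dpois(0:15, par$lambda), tolerance = 1e-12)
  expect_error(lethality_joint_pmf(par, 2L, 3L, 0L), "exceed")
})

test_that("survival closed form equals the truncated-sum oracle", {
  expect_equal(uv_survival(lethality_params(0, 0, 0)), 1)
  for (lam in c(0.5, 3.478, 10)) {
    for (gam in c(0, 1, 8.8625)) {
      par <- lethality_params(lam, 0.1, gam)
      expect_equal(uv_survival(par), oracle_survival(par), tolerance = 1e-10)
    }
  }
  # headline regime: S ~ 1e-4
  par <- lethality_params(3.478, 0.1, 8.8625)
  expect_equal(uv_survival(par), 1e-4, tolerance = 0.01)
})

test_that("survivor mutation load equals lambda(1-l) and the oracle", {
  expect_equal(mean_mutations_survivor(lethality_params(5, 1, 2)), 0)
  par <- lethality_params(3.478, 0.1, 8.8625)
  expect_equal(mean_mutations_survivor(par), 3.13, tolerance = 1e-3)
  for (lam in c(0.5, 3.478, 9)) {
    p <- lethality_params(lam, 0.25, 2)
    expect_equal(mean_mutations_survivor(p), oracle_rho_survivor(p),
                 tolerance = 1e-9)
  }
})

test_that("parameter inversion matches the published-regime algebra", {
  par <- invert_lethality(S = 1e-4, rho = 3.13, l = 0.1)
  expect_equal(round(par$lambda * par$l, 2), 0.35)
  expect_equal(round(par$gamma, 2), 8.86)
  expect_equal(round(mutation_efficiency(par$lambda * par$l, par$gamma), 3),
               0.038)
  # l = 0 collapses to lambda = rho, gamma = -ln S
  par0 <- invert_lethality(1e-3, 2.5, 0)
  expect_equal(par0$lambda, 2.5)
  expect_equal(par0$gamma, -log(1e-3))
  expect_error(invert_lethality(S = 0.9, rho = 50, l = 0.5), "inconsistent")
})

test_that("inversion is the exact inverse of the forward maps", {
  for (lam in c(0.8, 3.478)) {
    for (l in c(0, 0.1, 0.6)) {
      par <- lethality_params(lam, l, 2.2)
      back <- invert_lethality(uv_survival(par), mean_mutations_survivor(par),
                               l)
      expect_equal(back$lambda, par$lambda, tolerance = 1e-12)
      expect_equal(back$gamma, par$gamma, tolerance = 1e-12)
    }
  }
})

test_that("efficiency: scale invariance, limits and the mutator value", {
  expect_equal(round(mutation_efficiency(0.3478, 8.8625), 3), 0.038)
  expect_equal(mutation_efficiency(0.5, 0), 1)
  expect_equal(mutation_efficiency(0.3, 0.7),
               mutation_efficiency(3, 7), tolerance = 1e-15)
  # gamma proportional to lambda: efficiency = l / (l + gamma/lambda)
  expect_equal(round(0.1 / (0.1 + 4.85), 3), 0.020)
  expect_error(mutation_efficiency(0, 0), "positive")
})

test_that("Monte Carlo forward simulation reproduces S and rho", {
  par <- lethality_params(3.478, 0.1, 6)
  sim <- simulate_survival(par, cells = 3e5, seed = 111L)
  S <- uv_survival(par)
  se_S <- sqrt(S * (1 - S) / sim$cells)
  expect_lt(abs(sim$S_hat - S), 3 * se_S)
  rho <- mean_mutations_survivor(par)
  se_rho <- sqrt(rho / sim$survivors)
  expect_lt(abs(sim$rho_hat - rho), 3 * se_rho)
})

test_that("mutator growth-defect fit recovers gamma/lambda", {
  lam <- c(0.5, 1, 2, 4, 8) * 1e-3
  c_true <- 4.85; l <- 0.1; mu_wt <- 0.8
  mu <- mu_wt * exp(-lam * (l + c_true))
  fit <- fit_mutator_gamma(lam, mu, mu_wt, l = l)
  expect_equal(fit$c, c_true, tolerance = 1e-6)
  expect_equal(round(fit$efficiency, 3), 0.020)
  # a lambda = 0 strain is predicted to grow at the wild-type rate
  expect_equal(fit_mutator_gamma(c(0, lam), c(mu_wt, mu), mu_wt,
                                 l = l)$fitted[1], 0)
  # noise inflates the standard error monotonically
  ses <- vapply(c(0.002, 0.01, 0.05), function(s) {
    set.seed(112L)
    fit_mutator_gamma(lam, mu * exp(rnorm(5, 0, s)), mu_wt, l = l)$se
  }, numeric(1))
  expect_true(all(diff(ses) > 0))
  expect_error(fit_mutator_gamma(c(0, 0), c(1, 1), 1), "unidentifiable")
})
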