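test_that("recency weights follow the quartic-root formula", {
  expect_equal(regression_weights(1), 1)
  w <- regression_weights(6)
  expect_equal(w[6], 1)
  expect_equal(w[3], (1 + 9 / 32)^(-1 / 4), tolerance = 1e-12)
  expect_equal(w[3], 0.9399, tolerance = 1e-4)
  expect_true(all(diff(w) > 0))  # strictly decreasing in T - t
})

test_that("bias regression recovers C on noiseless kappa = 1 data", {
  rho <- 0.5
  gam <- 0.3 * rho^(1:5)
  C <- 0.5
  delta <- C * gam^2 * (1 / rho - 1)^2
  fit <- fit_skl_regression(delta, gam, rho, "kappa_fixed_1")
  expect_equal(fit$kappa_hat, 1)
  expect_lt(abs(fit$C_hat - C) / C, 0.05)
  # self-consistency: the pipeline reproduces the generative SKL law
  for (g in gam) {
    expect_equal(estimate_skl_to_opt(fit, g), C * g^2, tolerance = 0.02)
  }
})

test_that("bias regression recovers kappa on noiseless kappa-free data", {
  rho <- 0.5
  kap <- 0.7; C <- 2
  gam <- 0.3 * rho^(1:6)
  delta <- C * gam^(2 * kap) * (1 / rho^kap - 1)^2
  fit <- fit_skl_regression(delta, gam, rho, "kappa_free")
  expect_lt(abs(fit$kappa_hat - kap), 0.05)
  expect_lt(abs(fit$C_hat - C) / C, 0.1)
})

test_that("a single observation puts the posterior mode at the implied C", {
  rho <- 0.5
  d1 <- 0.02; g1 <- 0.1
  fit <- fit_skl_regression(d1, g1, rho, "kappa_fixed_1")
  implied <- log(d1) - 2 * log(1 / rho - 1) - 2 * log(g1)
  expect_lt(abs(fit$logC_mode - implied), 0.02)
  # rho = 0.5, kappa = 1: estimate at gamma equals delta itself (up to the
  # weak-prior pull on the posterior mean)
  expect_equal(estimate_skl_to_opt(fit, g1), d1, tolerance = 0.06)
})

test_that("posterior means agree with an independent wide-grid oracle", {
  rho <- 0.5
  gam <- 0.3 * rho^(1:6)
  set.seed(71)
  delta <- 1.3 * gam^2 * (1 / rho - 1)^2 * exp(rnorm(6, sd = 0.3))
  fit <- fit_skl_regression(delta, gam, rho, "kappa_fixed_1")
  oracle <- naive_skl_posterior(delta, gam, rho, kappa_grid = 1)
  expect_lt(abs(fit$C_hat - oracle$C_hat) / oracle$C_hat, 0.02)

  kap <- 0.8
  delta_k <- 1.3 * gam^(2 * kap) * (1 / rho^kap - 1)^2 * exp(rnorm(6, sd = 0.2))
  fit_k <- fit_skl_regression(delta_k, gam, rho, "kappa_free")
  oracle_k <- naive_skl_posterior(
    delta_k, gam, rho, kappa_grid = seq(0.0025, 0.9975, by = 0.005),
    logC_grid = seq(-12, 12, by = 0.05), logsig_grid = seq(-7, 3, by = 0.05))
  expect_lt(abs(fit_k$C_hat - oracle_k$C_hat) / oracle_k$C_hat, 0.02)
  expect_lt(abs(fit_k$kappa_hat - oracle_k$kappa_hat), 0.01)
})

test_that("degenerate observations are rejected or dropped", {
  expect_error(fit_skl_regression(numeric(0), numeric(0), 0.5, "kappa_fixed_1"),
               "too few")
  expect_error(fit_skl_regression(c(0.1, 0.2), c(0.1, 0.05), 0.5, "kappa_free"),
               "too few")
  expect_warning(
    fit <- fit_skl_regression(c(0.1, -1, 0.05), c(0.2, 0.1, 0.05), 0.5,
                              "kappa_fixed_1"),
    "dropped")
  expect_equal(length(fit$delta), 2L)
})

test_that("SKL extrapolation follows the fitted power law", {
  rho <- 0.5
  gam <- 0.3 * rho^(1:4)
  delta <- 2 * gam^2 * (1 / rho - 1)^2
  fit <- fit_skl_regression(delta, gam, rho, "kappa_fixed_1")
  expect_gt(estimate_skl_to_opt(fit, 0.2), 0)
  # gamma -> 0 monotone decrease; doubling gamma quadruples the estimate
  gs <- c(0.2, 0.1, 0.05, 0.025)
  ests <- vapply(gs, function(g) estimate_skl_to_opt(fit, g), numeric(1))
  expect_true(all(diff(ests) < 0))
  expect_equal(estimate_skl_to_opt(fit, 0.2) / estimate_skl_to_opt(fit, 0.1),
               4, tolerance = 1e-10)
})

test_that("iteration model is exact on noiseless power-law data", {
  gam <- c(0.3, 0.15, 0.075)
  im <- fit_iteration_model(100 / gam, gam, gamma_next = 0.0375)
  expect_equal(im$alpha_hat, -1, tolerance = 1e-10)
  expect_equal(im$beta_hat, log(100), tolerance = 1e-10)
  expect_equal(im$K_next_hat, 100 / 0.0375, tolerance = 1e-8)
  expect_false(im$heuristic)

  im_const <- fit_iteration_model(rep(500, 4), 0.3 * 0.5^(0:3), 0.3 * 0.5^4)
  expect_equal(im_const$alpha_hat, 0, tolerance = 1e-10)
  expect_equal(im_const$K_next_hat, 500, tolerance = 1e-8)

  im_h <- fit_iteration_model(1000, 0.3, 0.15)
  expect_true(im_h$heuristic)
  expect_equal(im_h$K_next_hat, 2000)
})

test_that("iteration model predicts within 25% under mild log-noise", {
  set.seed(72)
  gam <- 0.3 * 0.5^(0:5)
  ok <- 0L
  for (s in 1:100) {
    K <- 100 / gam * exp(rnorm(6, sd = 0.1))
    im <- fit_iteration_model(K, gam, gamma_next = 0.3 * 0.5^6)
    if (abs(im$K_next_hat - 100 / (0.3 * 0.5^6)) / (100 / (0.3 * 0.5^6)) < 0.25)
      ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("inefficiency index composes RSKL and RI as documented", {
  fit <- structure(list(C_hat = 1, kappa_hat = 1), class = "skl_fit")
  dec <- inefficiency(fit, K_next_hat = 3000, K_gamma_t = 1000, gamma_t = 0.1,
                      xi = 0.1, rho = 0.5, K0 = 1000, tau_threshold = 1)
  expect_equal(dec$RSKL_hat, 1.5)
  expect_equal(dec$RI_hat, 1.5)
  expect_equal(dec$I_hat, 2.25)
  expect_true(dec$terminate)
  expect_equal(dec$I_hat, dec$RSKL_hat * dec$RI_hat)

  # xi = 0 limit: RSKL = rho^kappa < 1 regardless of C and gamma
  dec0 <- inefficiency(structure(list(C_hat = 42, kappa_hat = 0.7),
                                 class = "skl_fit"),
                       1000, 1000, 0.01, xi = 1e-12, rho = 0.5, K0 = 1000)
  expect_equal(dec0$RSKL_hat, 0.5^0.7, tolerance = 1e-6)

  # monotonicity: larger tau never triggers earlier; RSKL increasing in xi,
  # decreasing in gamma * sqrt(C)
  expect_false(inefficiency(fit, 3000, 1000, 0.1, 0.1, 0.5, 1000,
                            tau_threshold = 3)$terminate)
  for (xi in c(0.05, 0.1, 0.2, 0.4)) {
    r1 <- inefficiency(fit, 1, 1, 0.1, xi, 0.5, 1)$RSKL_hat
    r2 <- inefficiency(fit, 1, 1, 0.1, xi * 2, 0.5, 1)$RSKL_hat
    expect_gt(r2, r1)
  }
  for (g in c(0.05, 0.1, 0.2)) {
    r1 <- inefficiency(fit, 1, 1, g, 0.1, 0.5, 1)$RSKL_hat
    r2 <- inefficiency(fit, 1, 1, 2 * g, 0.1, 0.5, 1)$RSKL_hat
    expect_lt(r2, r1)
  }
})
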