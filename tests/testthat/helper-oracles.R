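# Independent oracles, coded without reference to the package internals.

# Split-R-hat by the textbook two-chain formulas (no shared code with
# split_rhat(): explicit between/within variance decomposition).
brute_rhat <- function(x) {
  W <- length(x)
  n <- W %/% 2
  ch <- cbind(x[1:n], x[(W - n + 1):W])
  psi_j <- colMeans(ch)
  psi <- mean(psi_j)
  B <- n / (2 - 1) * sum((psi_j - psi)^2)
  Wv <- mean(apply(ch, 2, var))
  sqrt(((n - 1) / n * Wv + B / n) / Wv)
}

# ESS by direct O(n * L) autocovariance sums on the split chain with
# Geyer's initial monotone positive-sequence rule.
brute_ess <- function(x) {
  N <- length(x)
  n <- N %/% 2
  chains <- list(x[1:n], x[(N - n + 1):N])
  acov <- sapply(chains, function(y) {
    yc <- y - mean(y)
    sapply(0:(n - 1), function(t)
      sum(yc[1:(n - t)] * yc[(1 + t):n]) / n)
  })
  mean_var <- mean(acov[1, ]) * n / (n - 1)
  var_plus <- mean_var * (n - 1) / n + var(sapply(chains, mean))
  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus
  tau <- -1
  prev <- Inf
  for (k in seq_len(n %/% 2)) {
    i <- 2 * (k - 1) + 1
    p <- rho[i] + if (i + 1 <= n) rho[i + 1] else 0
    if (k > 1 && p < 0) break
    p <- min(p, prev)
    prev <- p
    tau <- tau + 2 * p
  }
  tau <- max(tau, 1 / log10(N + 1))
  2 * n / tau
}

# Monte Carlo symmetrized KL between two mean-field Gaussians.
mc_skl <- function(p1, p2, n) {
  x1 <- mf_sample(p1, n)
  x2 <- mf_sample(p2, n)
  a <- mf_log_q(p1, x1) - mf_log_q(p2, x1)
  b <- mf_log_q(p2, x2) - mf_log_q(p1, x2)
  list(est = mean(a) + mean(b),
       se = sqrt(var(a) / n + var(b) / n))
}

# Central finite-difference gradient of a scalar function.
num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    hp <- h * (1 + abs(x[i]))
    up <- x; up[i] <- up[i] + hp
    dn <- x; dn[i] <- dn[i] - hp
    (f(up) - f(dn)) / (2 * hp)
  }, numeric(1))
}

# Naive wide fixed-grid posterior for the SKL bias regression (oracle for
# fit_skl_regression; shares no code with the package's refined-grid path).
naive_skl_posterior <- function(delta, gamma, rho, kappa_grid = 1,
                                logC_grid = seq(-15, 15, by = 0.02),
                                logsig_grid = seq(-10, 3, by = 0.02)) {
  w <- (1 + (length(delta) - seq_along(delta))^2 / 32)^(-1 / 4)
  y <- log(delta); lg <- log(gamma)
  nk <- length(kappa_grid)
  tot <- 0
  sC <- 0; sK <- 0
  maxlp <- -Inf
  lp_store <- vector("list", nk)
  for (ik in seq_len(nk)) {
    kap <- kappa_grid[ik]
    mu0 <- 2 * log(1 / rho^kap - 1) + 2 * kap * lg
    lp <- matrix(0, length(logC_grid), length(logsig_grid))
    for (j in seq_along(logsig_grid)) {
      s <- exp(logsig_grid[j])
      ll <- vapply(logC_grid, function(u)
        sum(w * dnorm(y, u + mu0, s, log = TRUE)), numeric(1))
      lp[, j] <- ll + dcauchy(logC_grid, 0, 10, log = TRUE) +
        dcauchy(s, 0, 10, log = TRUE) + log(2) + logsig_grid[j]
    }
    lp_store[[ik]] <- lp
    maxlp <- max(maxlp, max(lp))
  }
  for (ik in seq_len(nk)) {
    p <- exp(lp_store[[ik]] - maxlp)
    tot <- tot + sum(p)
    sC <- sC + sum(rowSums(p) * logC_grid)
    sK <- sK + sum(p) * kappa_grid[ik]
  }
  list(C_hat = exp(sC / tot), kappa_hat = sK / tot)
}

# Small helpers used across files.
toy_trace <- function(k, m, seed = 1) {
  set.seed(seed)
  matrix(rnorm(k * m), k, m)
}
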