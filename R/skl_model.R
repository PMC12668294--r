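#' Recency weights for the low-data regressions
#'
#' `w_t = (1 + (T - t)^2 / 32)^(-1/4)` for `t = 1..T`: the most recent
#' observation gets weight 1 and earlier ones are down-weighted gradually
#' (noticeably after about 3 observations), because early symmetrized-KL
#' and convergence-iteration measurements are contaminated by higher-order
#' bias terms.
#'
#' @param T Number of observations.
#' @return Numeric vector of length `T`.
#' @export
regression_weights <- function(T) {
  stopifnot(T >= 1)
  t <- seq_len(T)
  (1 + (T - t)^2 / 32)^(-1 / 4)
}

# Half-Cauchy(0, scale) log-density of sigma = exp(v), including the
# log-scale Jacobian.
log_prior_logsigma <- function(v, scale = 10) {
  stats::dcauchy(exp(v), 0, scale, log = TRUE) + log(2) + v
}

#' Fit the symmetrized-KL bias regression
#'
#' Fits the power-law bias model
#' `log delta_t = log C + 2 log(1/rho^kappa - 1) + 2 kappa log gamma_t +
#' eta_t`, `eta_t ~ N(0, sigma^2)`, to the sequence of symmetrized KL
#' divergences `delta_t` between variational approximations obtained at
#' successive learning rates `gamma_t = gamma_0 rho^t`. Each observation's
#' log-likelihood term is tempered by the recency weight
#' [regression_weights()]. Priors: `log C ~ Cauchy(0, 10)`,
#' `sigma ~ Cauchy+(0, 10)`, and `kappa ~ Unif(0, 1)` in `kappa_free` mode;
#' `kappa_fixed_1` pins `kappa = 1` (appropriate for averaged adaptive
#' optimizers with a mean-field Gaussian family, where the stationary bias
#' is linear in the learning rate).
#'
#' The posterior is computed by deterministic mode-region grid quadrature
#' over `(log C, log sigma)` (plus a `kappa` grid in `kappa_free` mode),
#' with range-refinement passes; the numerical error of the posterior means
#' is far below the 2% accuracy this estimate needs. `C_hat` is
#' `exp(E[log C])` (the geometric posterior mean), which is stable in the
#' low-data regime where `E[C]` would be dominated by the heavy upper tail.
#'
#' @param delta Positive SKL observations `delta_t` (t = 1..T, oldest
#'   first). Nonpositive values are dropped with a warning.
#' @param gamma Learning rates `gamma_t` matching `delta`.
#' @param rho Learning-rate adaptation factor in (0, 1).
#' @param mode `"kappa_fixed_1"` (needs >= 1 observation) or `"kappa_free"`
#'   (needs >= 3).
#' @return Object of class `"skl_fit"`: `C_hat`, `kappa_hat`, `logC_mean`,
#'   `logC_mode`, `sigma_mean`, `mode`, the marginals of `log C` (and
#'   `kappa`), the weights used, and the retained data.
#' @export
fit_skl_regression <- function(delta, gamma, rho,
                               mode = c("kappa_fixed_1", "kappa_free")) {
  mode <- match.arg(mode)
  stopifnot(length(delta) == length(gamma), rho > 0, rho < 1)
  keep <- delta > 0
  if (any(!keep)) {
    warning(sum(!keep), " nonpositive delta observation(s) dropped")
    delta <- delta[keep]; gamma <- gamma[keep]
  }
  T <- length(delta)
  need <- if (mode == "kappa_fixed_1") 1L else 3L
  if (T < need)
    stop("too few SKL observations for mode ", mode, " (need ", need, ")")
  w <- regression_weights(T)
  y <- log(delta)
  lg <- log(gamma)

  kappa_grid <- if (mode == "kappa_fixed_1") 1
                else seq(0.0025, 0.9975, by = 0.005)
  A <- sum(w)
  # per-kappa implied-logC sufficient statistics
  stats_k <- lapply(kappa_grid, function(kap) {
    z <- y - 2 * log(1 / rho^kap - 1) - 2 * kap * lg
    B <- sum(w * z); Cc <- sum(w * z^2)
    list(B = B, Cc = Cc, center = B / A,
         s = sqrt(max(Cc - B^2 / A, 0) / A))
  })
  centers <- vapply(stats_k, `[[`, numeric(1), "center")
  s_all <- vapply(stats_k, `[[`, numeric(1), "s")
  s_max <- max(s_all)

  # initial grids
  pad <- max(10, 10 * s_max)
  u_range <- c(min(centers) - pad, max(centers) + pad)       # log C
  v_range <- c(log(max(min(s_all), 1e-8)) - 4, log(50))      # log sigma
  nu <- 121L; nv <- 101L

  eval_post <- function(u, v) {
    # returns list(post = array [nu, nv, nk] of unnormalized posterior,
    # on the log scale shifted by its max)
    nk <- length(kappa_grid)
    lp <- array(NA_real_, c(length(u), length(v), nk))
    pr_u <- stats::dcauchy(u, 0, 10, log = TRUE)
    pr_v <- log_prior_logsigma(v)
    inv2s2 <- 1 / (2 * exp(2 * v))
    for (ik in seq_len(nk)) {
      st <- stats_k[[ik]]
      sse <- A * u^2 - 2 * st$B * u + st$Cc
      lp[, , ik] <- outer(-sse, inv2s2) +
        matrix(rep(-A * (v + 0.5 * log(2 * pi)) + pr_v, each = length(u)),
               length(u)) + pr_u
    }
    lp
  }

  for (pass in 1:4) {
    u <- seq(u_range[1], u_range[2], length.out = nu)
    v <- seq(v_range[1], v_range[2], length.out = nv)
    lp <- eval_post(u, v)
    lp <- lp - max(lp)
    post <- exp(lp)
    post <- post / sum(post)
    mu <- apply(post, 1, sum)  # marginal of log C
    if (pass == 4L) break
    # shrink (or keep) the logC range to the region holding the mass
    cmu <- cumsum(mu)
    lo_i <- max(1L, which(cmu > 1e-10)[1] - 2L)
    hi_i <- min(nu, which(cmu > 1 - 1e-10)[1] + 2L)
    if (mu[1] > 1e-6 || mu[nu] > 1e-6) {
      # mass at the edge: expand instead
      width <- u_range[2] - u_range[1]
      u_range <- c(u_range[1] - width, u_range[2] + width)
    } else if (hi_i - lo_i < nu - 5L) {
      u_range <- c(u[lo_i], u[hi_i])
    } else break
  }

  mv <- apply(post, 2, sum)
  logC_mean <- sum(mu * u)
  logC_mode <- u[which.max(mu)]
  sigma_mean <- sum(mv * exp(v))
  if (mode == "kappa_fixed_1") {
    kappa_hat <- 1
    mk <- NULL
  } else {
    mk <- apply(post, 3, sum)
    kappa_hat <- sum(mk * kappa_grid)
  }
  structure(list(
    C_hat = exp(logC_mean), kappa_hat = kappa_hat,
    logC_mean = logC_mean, logC_mode = logC_mode, sigma_mean = sigma_mean,
    mode = mode, weights = w, delta = delta, gamma = gamma, rho = rho,
    marginal_logC = list(value = u, prob = mu),
    marginal_kappa = if (!is.null(mk)) list(value = kappa_grid, prob = mk)),
    class = "skl_fit")
}

#' Estimated symmetrized KL to the optimum
#'
#' Extrapolates the fitted bias model to learning rate `gamma`:
#' `SKL(q_gamma, q*) ~= C_hat * gamma^(2 kappa_hat)`. With `kappa = 1` and a
#' single observation `delta`, this reduces to
#' `delta * rho^2 / (1 - rho)^2`.
#'
#' @param fit An `"skl_fit"`.
#' @param gamma Learning rate (`> 0`).
#' @return The estimated symmetrized KL divergence.
#' @export
estimate_skl_to_opt <- function(fit, gamma) {
  stopifnot(gamma > 0)
  fit$C_hat * gamma^(2 * fit$kappa_hat)
}

#' Fit the convergence-iteration model
#'
#' Weighted least squares for `log K_gamma = alpha log gamma + beta`, with
#' the recency weights of [regression_weights()], and prediction of the
#' iteration count at the next learning rate,
#' `K_next_hat = gamma_next^alpha_hat * exp(beta_hat)`. With fewer than two
#' records the power law cannot be fitted and the heuristic
#' `K_next_hat = K[T] / rho_eff` (with `rho_eff = gamma_next / gamma[T]`) is
#' returned, flagged as such.
#'
#' @param K Iteration counts per epoch (oldest first).
#' @param gamma Matching learning rates.
#' @param gamma_next Learning rate to predict for.
#' @return List with `alpha_hat`, `beta_hat`, `K_next_hat`, `heuristic`.
#' @export
fit_iteration_model <- function(K, gamma, gamma_next) {
  stopifnot(length(K) == length(gamma), all(K > 0), all(gamma > 0),
            gamma_next > 0)
  T <- length(K)
  if (T < 2L) {
    return(list(alpha_hat = NA_real_, beta_hat = NA_real_,
                K_next_hat = K[T] * gamma[T] / gamma_next, heuristic = TRUE))
  }
  w <- regression_weights(T)
  fit <- stats::lm(log(K) ~ log(gamma), weights = w)
  alpha <- unname(stats::coef(fit)[2])
  beta <- unname(stats::coef(fit)[1])
  list(alpha_hat = alpha, beta_hat = beta,
       K_next_hat = gamma_next^alpha * exp(beta), heuristic = FALSE)
}

#' Inefficiency index and termination decision
#'
#' Combines the estimated relative SKL improvement
#' `RSKL_hat = rho^kappa_hat + xi / (C_hat^(1/2) gamma_t^kappa_hat)` with
#' the relative iteration increase `RI_hat = K_next_hat / (K_gamma_t + K0)`
#' into the inefficiency index `I_hat = RSKL_hat * RI_hat`. Optimization
#' terminates when `I_hat > tau_threshold`: the predicted increase in
#' runtime outweighs the predicted reduction in error (relative to the
#' accuracy target `xi`), which happens roughly when the square root of the
#' SKL to the optimum reaches `xi`.
#'
#' @param fit An `"skl_fit"` (supplies `C_hat`, `kappa_hat`).
#' @param K_next_hat Predicted iterations to converge at the next rate.
#' @param K_gamma_t Iterations used at the current rate.
#' @param gamma_t Current learning rate.
#' @param xi Accuracy threshold for `sqrt(SKL)`.
#' @param rho Learning-rate adaptation factor.
#' @param K0 Iteration count the user considers small.
#' @param tau_threshold Inefficiency threshold (terminate when exceeded).
#' @return Object of class `"termination_decision"` with `RSKL_hat`,
#'   `RI_hat`, `I_hat`, `K_next_hat`, `terminate`, and the echoed
#'   `xi`, `tau_threshold`, `K0`.
#' @export
inefficiency <- function(fit, K_next_hat, K_gamma_t, gamma_t, xi, rho, K0,
                         tau_threshold = 1) {
  stopifnot(K_next_hat > 0, K_gamma_t > 0, gamma_t > 0, xi > 0, K0 > 0,
            rho > 0, rho < 1)
  kap <- fit$kappa_hat
  RSKL_hat <- rho^kap + xi / (sqrt(fit$C_hat) * gamma_t^kap)
  RI_hat <- K_next_hat / (K_gamma_t + K0)
  I_hat <- RSKL_hat * RI_hat
  structure(list(RSKL_hat = RSKL_hat, RI_hat = RI_hat, I_hat = I_hat,
                 K_next_hat = K_next_hat, terminate = I_hat > tau_threshold,
                 xi = xi, tau_threshold = tau_threshold, K0 = K0),
            class = "termination_decision")
}
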