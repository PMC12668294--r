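#' RABVI configuration
#'
#' Tuning parameters of the full framework, with the recommended defaults.
#' The only parameters a user is expected to adjust are the accuracy
#' threshold `xi` (target for the square root of the symmetrized KL to the
#' optimal approximation), the inefficiency threshold `tau_threshold`
#' (accuracy/computation trade-off; 1 weights them equally), and the global
#' iteration budget `Kmax`.
#'
#' @param xi Accuracy threshold (`> 0`), default 0.1.
#' @param tau_threshold Inefficiency threshold, default 1.
#' @param Kmax Global iteration budget, default 100000.
#' @param gamma0 Initial learning rate, default 0.3.
#' @param Wmin Minimum stationarity window, default 200.
#' @param K0 "Small" iteration count, default `5 * Wmin = 1000`.
#' @param eps0 Initial iterate-average relative-error threshold, default
#'   `xi`.
#' @param rho Learning-rate adaptation factor in (0, 1), default 0.5.
#' @param M Monte Carlo draws per gradient, default 10.
#' @param optimizer Optimizer method, default `"avg_adam"`.
#' @param family Variational family kind, default `"mean_field_gaussian"`.
#'   Families without a closed-form symmetrized KL (e.g. normalizing flows)
#'   are rejected; the full-rank Gaussian has a closed form but is not on
#'   the supported optimization path.
#' @param seed Integer seed; all randomness derives from it.
#' @param eps_decay Multiplicative decay of the gate threshold per epoch,
#'   default 1 (constant threshold).
#' @param kappa_mode `"auto"` picks `kappa_fixed_1` for averaged adaptive
#'   optimizers with the mean-field family and `kappa_free` otherwise.
#' @param cost_ratio Fixed check-schedule cost ratio; `NULL` (default)
#'   estimates it from measured runtimes each epoch.
#' @return Object of class `"rabvi_config"`.
#' @export
rabvi_config <- function(xi = 0.1, tau_threshold = 1, Kmax = 100000L,
                         gamma0 = 0.3, Wmin = 200L, K0 = 5L * Wmin,
                         eps0 = xi, rho = 0.5, M = 10L,
                         optimizer = "avg_adam",
                         family = "mean_field_gaussian",
                         seed = 1L, eps_decay = 1,
                         kappa_mode = c("auto", "kappa_fixed_1", "kappa_free"),
                         cost_ratio = NULL) {
  kappa_mode <- match.arg(kappa_mode)
  if (family %in% c("real_nvp", "flow", "normalizing_flow"))
    stop("family '", family, "' has no closed-form symmetrized KL; ",
         "the termination rule requires one")
  if (family == "full_rank_gaussian")
    stop("full-rank Gaussian is not on the supported optimization path ",
         "(closed-form SKL is available but gradients/driver support only ",
         "the mean-field family)")
  if (family != "mean_field_gaussian") stop("unknown family: ", family)
  optimizer <- match.arg(optimizer, optimizer_methods())
  stopifnot(xi > 0, tau_threshold > 0, Kmax >= 1, gamma0 > 0, Wmin >= 8,
            K0 > 0, eps0 > 0, rho > 0, rho < 1, M >= 1,
            eps_decay > 0, eps_decay <= 1)
  structure(list(xi = xi, tau_threshold = tau_threshold,
                 Kmax = as.integer(Kmax), gamma0 = gamma0,
                 Wmin = as.integer(Wmin), K0 = as.integer(K0), eps0 = eps0,
                 rho = rho, M = as.integer(M), optimizer = optimizer,
                 family = family, seed = as.integer(seed),
                 eps_decay = eps_decay, kappa_mode = kappa_mode,
                 cost_ratio = cost_ratio),
            class = "rabvi_config")
}

# Deterministic per-epoch seed derived from the base seed (kept < 2^31).
epoch_seed <- function(seed, t) {
  as.integer((as.double(seed) * 7919 + 104729 * (t + 1)) %% 2147483647)
}

#' Run robust and automated black-box variational inference
#'
#' The outer loop of the framework: epochs of fixed-learning-rate automated
#' stochastic optimization ([run_faso()]) at learning rates
#' `gamma_t = gamma0 * rho^t`, each warm-started from the previous epoch's
#' iterate average. After every epoch `t >= 1` the closed-form symmetrized
#' KL `delta_t` between the successive iterate averages is recorded; once
#' enough observations exist (2 for `kappa_fixed_1`, 3 for `kappa_free`)
#' the bias regression ([fit_skl_regression()]) and iteration model
#' ([fit_iteration_model()]) are fitted and the termination rule
#' ([inefficiency()]) is evaluated. The run stops when the rule triggers or
#' the global budget `Kmax` is exhausted (with a warning).
#'
#' @param target A `"target_distribution"` or a target key string (see
#'   [resolve_target()]).
#' @param config A [rabvi_config()].
#' @param lambda_init Initial flat parameters (default: zero location, zero
#'   log-scale).
#' @param init_with_rmsprop Stabilization pass: use RMSProp instead of the
#'   configured optimizer for the first epoch only (useful for harder
#'   targets; off by default).
#' @param verbose Emit per-epoch log lines.
#' @return Object of class `"rabvi_result"`: `params_hat` / `lambda_hat`
#'   (final iterate average), `epochs` (data frame of per-epoch records),
#'   `decisions` (list of `"termination_decision"`), `skl_fit`, `iter_fit`,
#'   `est_sqrt_skl_to_opt`, `status` (`"terminated_by_rule"` or
#'   `"budget_exhausted_warning"`), `total_iterations`, and the echoed
#'   `config`.
#' @export
run_rabvi <- function(target, config = rabvi_config(),
                      lambda_init = NULL, init_with_rmsprop = FALSE,
                      verbose = FALSE) {
  if (is.character(target)) target <- resolve_target(target)
  stopifnot(inherits(target, "target_distribution"))
  d <- target$dim
  fam <- family_spec(config$family, d)
  mode <- if (config$kappa_mode == "auto") {
    if (config$family == "mean_field_gaussian" &&
        config$optimizer %in% c("avg_adam", "avg_rmsprop"))
      "kappa_fixed_1" else "kappa_free"
  } else config$kappa_mode
  min_delta <- if (mode == "kappa_fixed_1") 2L else 3L

  lambda <- if (is.null(lambda_init)) rep(0, fam$n_params)
            else as.numeric(lambda_init)
  epochs <- list()
  decisions <- list()
  delta <- numeric(0)
  delta_gamma <- numeric(0)
  skl_fit <- NULL; iter_fit <- NULL
  total <- 0L
  t <- 0L
  status <- "budget_exhausted_warning"
  params_prev <- NULL

  repeat {
    gamma_t <- config$gamma0 * config$rho^t
    eps_t <- config$eps0 * config$eps_decay^t
    sd_t <- epoch_seed(config$seed, t)
    meth <- if (t == 0L && init_with_rmsprop) "rmsprop" else config$optimizer
    fr <- run_faso(target, gamma = gamma_t, epsilon = eps_t,
                   lambda_init = lambda, method = meth, M = config$M,
                   Wmin = config$Wmin,
                   Kmax_epoch = max(1L, config$Kmax - total),
                   seed = sd_t, family = fam,
                   cost_ratio = config$cost_ratio, verbose = verbose)
    total <- total + fr$K_gamma
    lambda <- fr$lambda_hat
    params_t <- fr$params_hat
    d_t <- if (t >= 1L) mf_skl(params_t, params_prev) else NA_real_
    epochs[[t + 1L]] <- data.frame(
      t = t, gamma = gamma_t, epsilon = eps_t, seed = sd_t,
      K_gamma = fr$K_gamma, kconv = fr$kconv, Wconv = fr$Wconv,
      kavg = fr$kavg, rhat = fr$rhat, converged = fr$converged,
      gate_passed = fr$gate_passed, delta = d_t)
    if (t >= 1L) {
      delta <- c(delta, d_t)
      delta_gamma <- c(delta_gamma, gamma_t)
    }
    params_prev <- params_t

    if (length(delta) >= min_delta) {
      skl_fit <- fit_skl_regression(delta, delta_gamma, config$rho, mode)
      Ks <- vapply(epochs, function(e) e$K_gamma, numeric(1))
      gs <- vapply(epochs, function(e) e$gamma, numeric(1))
      iter_fit <- fit_iteration_model(Ks, gs, gamma_next = config$rho * gamma_t)
      dec <- inefficiency(skl_fit, iter_fit$K_next_hat, fr$K_gamma, gamma_t,
                          xi = config$xi, rho = config$rho, K0 = config$K0,
                          tau_threshold = config$tau_threshold)
      decisions[[length(decisions) + 1L]] <- dec
      if (verbose)
        message(sprintf(
          "epoch %d: delta=%.3g RSKL=%.3g RI=%.3g I=%.3g terminate=%s",
          t, d_t, dec$RSKL_hat, dec$RI_hat, dec$I_hat, dec$terminate))
      if (dec$terminate) { status <- "terminated_by_rule"; break }
    }
    if (total >= config$Kmax) {
      warning("maximum number of iterations (Kmax = ", config$Kmax,
              ") reached before the termination rule triggered",
              call. = FALSE)
      break
    }
    t <- t + 1L
  }

  est <- if (!is.null(skl_fit))
    sqrt(estimate_skl_to_opt(skl_fit, config$gamma0 * config$rho^t))
  else NA_real_
  structure(list(
    lambda_hat = lambda, params_hat = params_prev,
    epochs = do.call(rbind, epochs), decisions = decisions,
    skl_fit = skl_fit, iter_fit = iter_fit,
    est_sqrt_skl_to_opt = est, status = status,
    total_iterations = total, config = config),
    class = "rabvi_result")
}

#' @export
print.rabvi_result <- function(x, ...) {
  cat("RABVI result:", x$status, "\n")
  cat("  epochs:", nrow(x$epochs),
      " total iterations:", x$total_iterations, "\n")
  cat("  final learning rate:", signif(min(x$epochs$gamma), 4), "\n")
  if (is.finite(x$est_sqrt_skl_to_opt))
    cat("  estimated sqrt SKL to optimum:",
        signif(x$est_sqrt_skl_to_opt, 4), "\n")
  invisible(x)
}

#' Serialize a RABVI result to JSON
#'
#' Writes the configuration echo, per-epoch records, termination decisions
#' and final parameters as structured JSON.
#'
#' @param result A `"rabvi_result"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rabvi_result <- function(result, path) {
  out <- list(
    status = result$status,
    total_iterations = result$total_iterations,
    est_sqrt_skl_to_opt = result$est_sqrt_skl_to_opt,
    config = unclass(result$config),
    epochs = result$epochs,
    decisions = lapply(result$decisions, unclass),
    lambda_hat = result$lambda_hat)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
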