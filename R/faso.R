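#' Check-scheduling constants
#'
#' The ESS/MCSE gate is evaluated on a geometric schedule of iteration
#' numbers `kconv + chi(r)^j * Wconv`, where `r` is the ratio of the
#' per-iterate cost of optimization to the per-iterate cost of the gate
#' check. `check_growth_factor()` returns the growth factor
#' `chi(r) = 1 + (1 + r)^(-1/2)`; `worst_case_cost_factor()` returns the
#' guarantee `g(r) = (2 + r + 2 sqrt(1 + r)) / (1 + r)`: checking on this
#' schedule costs at most a factor `g(r)` more than the clairvoyant schedule
#' that checks only at the first passing window. At `r = 0` these reduce to
#' the classical doubling trick, `chi(0) = 2` and `g(0) = 4`; `g` decreases
#' monotonically in `r`.
#'
#' @param r Cost ratio, `r >= 0`.
#' @return The factor value.
#' @export
check_growth_factor <- function(r) {
  stopifnot(all(r >= 0))
  1 + (1 + r)^(-1 / 2)
}

#' @rdname check_growth_factor
#' @export
worst_case_cost_factor <- function(r) {
  stopifnot(all(r >= 0))
  (2 + r + 2 * sqrt(1 + r)) / (1 + r)
}

#' Gate check schedule
#'
#' Iteration numbers at which the averaging gate is evaluated:
#' `kconv + round(chi(r)^j * Wconv)` for `j = 0, 1, ...`, strictly
#' increasing (duplicates after rounding are skipped), truncated to
#' `max_iter` (the first value beyond `max_iter` is included so a caller
#' can see the next scheduled check).
#'
#' @param r Cost ratio (`r = 0` recovers the doubling rule).
#' @param Wconv Window size at convergence detection.
#' @param kconv Iteration index at which the averaging window starts.
#' @param max_iter Largest iteration of interest.
#' @return Increasing integer vector of check iterations.
#' @export
check_schedule <- function(r, Wconv, kconv, max_iter = kconv + 1000L * Wconv) {
  stopifnot(r >= 0, Wconv >= 1)
  chi <- check_growth_factor(r)
  out <- integer(0)
  j <- 0
  last <- -Inf
  repeat {
    val <- kconv + round(chi^j * Wconv)
    if (val > last) {
      out <- c(out, val)
      last <- val
      if (val > max_iter) break
    }
    j <- j + 1
    if (j > 10000) break
  }
  out
}

#' Worst-case gate error factors
#'
#' Empirical verification of the guarantee behind the averaging gate. If
#' the iterate-average location and log-scale errors satisfy
#' `|tau_hat_i - tau_bar_i| <= eps * sigma_hat_i` and
#' `|psi_hat_i - psi_bar_i| <= eps` for some `eps` in (0, 1/2], then the
#' relative scale error is at most `(e^eps - 1)` and the relative location
#' error at most `eps * e^eps`. These functions compute, by dense grid
#' search over `eps` and the log-scale perturbation `delta`, the supremum
#' of those errors divided by `eps` — the constants that make "MCSE below
#' eps" translate into "relative parameter error below a small multiple of
#' eps" (printed bounds: 1.5 for the scale factor, 1.75 for the location
#' factor).
#'
#' @param eps_max Upper end of the `eps` range (default 0.5).
#' @param n_grid Grid resolution for both `eps` and `delta`.
#' @return The supremum of the error factor over the grid.
#' @export
worst_case_sd_error_factor <- function(eps_max = 0.5, n_grid = 2001L) {
  eps <- seq(eps_max / n_grid, eps_max, length.out = n_grid)
  worst <- vapply(eps, function(e) {
    delta <- seq(-e, e, length.out = 201L)
    max(abs(exp(delta) - 1)) / e
  }, numeric(1))
  max(worst)
}

#' @rdname worst_case_sd_error_factor
#' @export
worst_case_loc_error_factor <- function(eps_max = 0.5, n_grid = 2001L) {
  eps <- seq(eps_max / n_grid, eps_max, length.out = n_grid)
  worst <- vapply(eps, function(e) {
    delta <- seq(-e, e, length.out = 201L)
    max(e * exp(delta)) / e
  }, numeric(1))
  max(worst)
}

#' Iterate-averaging gate
#'
#' Decides whether an averaging window is long enough for the iterate
#' average to be trusted. For the mean-field Gaussian family the window
#' passes when the mean scaled location MCSE
#' `d^-1 sum_i MCSE(tau_i) / sigma_hat_i` and the mean log-scale MCSE
#' `d^-1 sum_i MCSE(psi_i)` are both below `epsilon`, where
#' `sigma_hat_i = exp(mean(psi_i))` over the window; for other families the
#' plainer condition `m^-1 sum_i MCSE(lambda_i) < epsilon` is used. In both
#' cases every coordinate must have an effective sample size of at least
#' `min_ess` (default 50) so the MCSE estimates themselves are reliable.
#'
#' @param window `k x m` iterate matrix (the candidate averaging window).
#' @param family A [family_spec()].
#' @param epsilon Relative-error threshold.
#' @param min_ess Minimum per-coordinate ESS.
#' @return List with `pass` plus the diagnostics (`mcse_loc_mean`,
#'   `mcse_psi_mean` or `mcse_mean`, and `ess_min`).
#' @export
mcse_gate <- function(window, family, epsilon, min_ess = 50) {
  stopifnot(nrow(window) >= 8)
  es <- ess_by_col(window)
  ess_min <- min(es)
  sds <- apply(window, 2, stats::sd)
  mc <- ifelse(sds == 0, 0, sds / sqrt(es))
  if (family$kind == "mean_field_gaussian") {
    d <- family$dim
    sigma_hat <- exp(colMeans(window[, d + seq_len(d), drop = FALSE]))
    mcse_loc <- mean(mc[seq_len(d)] / sigma_hat)
    mcse_psi <- mean(mc[d + seq_len(d)])
    pass <- (mcse_loc < epsilon) && (mcse_psi < epsilon) && (ess_min >= min_ess)
    list(pass = pass, mcse_loc_mean = mcse_loc, mcse_psi_mean = mcse_psi,
         ess_min = ess_min)
  } else {
    mcse_mean <- mean(mc)
    pass <- (mcse_mean < epsilon) && (ess_min >= min_ess)
    list(pass = pass, mcse_mean = mcse_mean, ess_min = ess_min)
  }
}

#' Fixed-learning-rate automated stochastic optimization (one epoch)
#'
#' Runs the chosen optimizer at a fixed learning rate `gamma`, detects
#' convergence of the iterate chain to stationarity (adaptive-window
#' split-R-hat below `rhat_threshold`, checked every `Wmin` iterations),
#' then keeps iterating and evaluates the ESS/MCSE gate ([mcse_gate()]) on
#' the geometric [check_schedule()] until the gate passes, at which point
#' the Polyak–Ruppert iterate average over the passing window is returned.
#' The schedule's cost ratio `r` is estimated from the measured wall time
#' of optimization iterations and of the first gate check.
#'
#' @param target A `"target_distribution"`.
#' @param gamma Fixed learning rate (`> 0`).
#' @param epsilon Gate threshold (`> 0`).
#' @param lambda_init Initial flat parameter vector (default: zero location
#'   and zero log-scale).
#' @param method Optimizer method (see [optimizer_state()]).
#' @param M Monte Carlo draws per gradient estimate.
#' @param Wmin Minimum stationarity-check window.
#' @param Kmax_epoch Iteration cap for this epoch; if reached, a best-effort
#'   average is returned with `converged`/`gate_passed` flags set
#'   accordingly.
#' @param seed Optional integer seed (recorded in the result so the epoch is
#'   exactly replayable).
#' @param family A [family_spec()]; only `"mean_field_gaussian"` is
#'   supported on the optimization path.
#' @param rhat_threshold Stationarity threshold on the worst-coordinate
#'   split-R-hat (default 1.1).
#' @param min_ess Minimum per-coordinate ESS for the gate.
#' @param gradient_fn Optional override returning the gradient for a flat
#'   parameter vector (either a numeric vector or a list with a `gradient`
#'   field); defaults to the reparameterization estimator. Useful for
#'   noiseless/deterministic runs.
#' @param cost_ratio Fixed cost ratio `r` for the check schedule. The
#'   default `NULL` estimates `r` from measured wall times (doubling rule
#'   until the first check has been timed); pass a number (e.g. 0) to make
#'   the schedule — and hence the whole epoch — fully reproducible.
#' @param return_trace Keep the full iterate trace in the result.
#' @param verbose Emit a one-line epoch log.
#' @return List of class `"faso_result"`: `lambda_hat` (flat vector),
#'   `params_hat` (`"mf_params"`), `K_gamma`, `kconv`, `Wconv`, `kavg`,
#'   `rhat`, `converged`, `gate_passed`, gate diagnostics, timing
#'   (`c_opt`, `c_check`, `r_used`), `seed`, and optionally `trace`.
#' @export
run_faso <- function(target, gamma, epsilon,
                     lambda_init = NULL,
                     method = "avg_adam", M = 10L, Wmin = 200L,
                     Kmax_epoch = 50000L, seed = NULL,
                     family = family_spec("mean_field_gaussian", target$dim),
                     rhat_threshold = 1.1, min_ess = 50,
                     gradient_fn = NULL, cost_ratio = NULL,
                     return_trace = FALSE, verbose = FALSE) {
  stopifnot(gamma > 0, epsilon > 0, Wmin >= 8, Kmax_epoch >= 1)
  if (family$kind != "mean_field_gaussian")
    stop("the optimization path supports only the mean-field Gaussian family")
  d <- target$dim
  m <- family$n_params
  if (!is.null(seed)) set.seed(seed)
  lambda <- if (is.null(lambda_init)) rep(0, m) else as.numeric(lambda_init)
  stopifnot(length(lambda) == m)
  if (is.null(gradient_fn)) {
    gradient_fn <- function(lam)
      reparam_grad(target, mf_from_vector(lam), M = M)$gradient
  }
  state <- optimizer_state(method, m)

  cap <- as.integer(min(Kmax_epoch, 4096L))
  trace <- matrix(NA_real_, cap, m)
  k <- 0L
  converged <- FALSE
  gate_passed <- FALSE
  kconv <- NA_integer_; Wconv <- NA_integer_; kavg <- NA_integer_
  rhat_at_conv <- NA_real_
  gate_diag <- NULL
  next_conv_check <- max(Wmin, ceiling(Wmin / 0.95))
  checks <- NULL; check_idx <- 1L
  measure_r <- is.null(cost_ratio)
  r_used <- if (measure_r) 0 else cost_ratio
  c_opt <- NA_real_; c_check <- NA_real_
  t_opt_total <- 0

  while (k < Kmax_epoch) {
    t0 <- proc.time()[["elapsed"]]
    g <- gradient_fn(lambda)
    if (is.list(g)) g <- g$gradient
    step <- tryCatch(opt_step(state, lambda, g, gamma), error = function(e) e)
    if (inherits(step, "error")) {
      # one retry from the last finite iterate with a fresh gradient draw
      g <- gradient_fn(lambda)
      if (is.list(g)) g <- g$gradient
      step <- tryCatch(opt_step(state, lambda, g, gamma), error = function(e) e)
      if (inherits(step, "error"))
        stop("optimization diverged at iteration ", k + 1L, " (gamma = ",
             signif(gamma, 3), "): ", conditionMessage(step))
    }
    state <- step$state
    lambda <- step$lambda
    k <- k + 1L
    if (k > nrow(trace)) {
      cap <- as.integer(min(Kmax_epoch, 2L * nrow(trace)))
      trace <- rbind(trace, matrix(NA_real_, cap - nrow(trace), m))
    }
    trace[k, ] <- lambda
    t_opt_total <- t_opt_total + (proc.time()[["elapsed"]] - t0)

    if (!converged) {
      if (k >= next_conv_check) {
        next_conv_check <- k + Wmin
        if (floor(0.95 * k) >= Wmin) {
          fw <- find_opt_window(trace[seq_len(k), , drop = FALSE], Wmin)
          # NaN means every coordinate is exactly constant over the window
          # (a noiseless chain at its fixed point): trivially stationary.
          if (is.nan(fw$rhat) ||
              (is.finite(fw$rhat) && fw$rhat <= rhat_threshold)) {
            converged <- TRUE
            Wconv <- as.integer(fw$Wopt)
            kconv <- k - Wconv + 1L
            rhat_at_conv <- fw$rhat
            c_opt <- t_opt_total / k
            checks <- check_schedule(r_used, Wconv, kconv - 1L,
                                     max_iter = Kmax_epoch)
            check_idx <- 1L
          }
        }
      }
    }
    if (converged && !gate_passed) {
      while (check_idx <= length(checks) && checks[check_idx] < k)
        check_idx <- check_idx + 1L
      if (check_idx <= length(checks) && checks[check_idx] == k) {
        win <- trace[kconv:k, , drop = FALSE]
        tc0 <- proc.time()[["elapsed"]]
        gd <- mcse_gate(win, family, epsilon, min_ess = min_ess)
        tc1 <- proc.time()[["elapsed"]]
        if (measure_r && is.na(c_check)) {
          # estimate r from measured costs, then reschedule remaining checks
          c_check <- max((tc1 - tc0) / nrow(win), .Machine$double.eps)
          r_used <- max(c_opt, 0) / c_check
          checks <- check_schedule(r_used, Wconv, kconv - 1L,
                                   max_iter = Kmax_epoch)
          check_idx <- which(checks > k)[1]
          if (is.na(check_idx)) check_idx <- length(checks) + 1L
        } else {
          check_idx <- check_idx + 1L
        }
        if (gd$pass) {
          gate_passed <- TRUE
          kavg <- k - kconv + 1L
          gate_diag <- gd
          break
        }
        gate_diag <- gd
      }
    }
  }

  if (!gate_passed) {
    # best effort: average over the detected (or best available) window
    if (!converged) {
      if (floor(0.95 * k) >= Wmin) {
        fw <- find_opt_window(trace[seq_len(k), , drop = FALSE], Wmin)
        Wconv <- as.integer(fw$Wopt)
        rhat_at_conv <- fw$rhat
      } else {
        Wconv <- max(4L, k %/% 2L)
      }
      kconv <- k - Wconv + 1L
    }
    kavg <- k - kconv + 1L
    if (kavg >= 8L)
      gate_diag <- mcse_gate(trace[kconv:k, , drop = FALSE], family, epsilon,
                             min_ess = min_ess)
  }
  rows <- kconv:(kconv + kavg - 1L)
  lambda_hat <- colMeans(trace[rows, , drop = FALSE])
  if (verbose)
    message(sprintf(
      "FASO gamma=%.4g kconv=%d Wconv=%d kavg=%d K=%d rhat=%.3f ess_min=%.0f",
      gamma, kconv, Wconv, kavg, k, rhat_at_conv,
      if (!is.null(gate_diag)) gate_diag$ess_min else NA_real_))
  structure(list(
    lambda_hat = lambda_hat,
    params_hat = if (family$kind == "mean_field_gaussian")
      mf_from_vector(lambda_hat) else NULL,
    K_gamma = k, kconv = kconv, Wconv = Wconv, kavg = kavg,
    rhat = rhat_at_conv, converged = converged, gate_passed = gate_passed,
    gate = gate_diag,
    timing = list(c_opt = c_opt, c_check = c_check, r_used = r_used),
    gamma = gamma, epsilon = epsilon, seed = seed,
    trace = if (return_trace) trace[seq_len(k), , drop = FALSE] else NULL),
    class = "faso_result")
}
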