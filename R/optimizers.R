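#' Fixed-learning-rate stochastic optimizer steps
#'
#' Implements the update `lambda <- lambda - gamma * d` for five choices of
#' descent direction `d`:
#' \describe{
#'   \item{sgd}{`d = g`, the raw stochastic gradient.}
#'   \item{rmsprop}{`d = g / (sqrt(v) + eps)` with `v` an exponential moving
#'     average (EMA) of the squared gradient.}
#'   \item{adam}{`d = m_hat / (sqrt(v_hat) + eps)` with EMAs of the gradient
#'     and squared gradient and the standard bias corrections.}
#'   \item{avg_rmsprop, avg_adam}{as rmsprop/adam, but the squared-gradient
#'     accumulator is the running average over all iterations,
#'     `v(k+1) = beta_k v(k) + (1 - beta_k) g^2` with `beta_k = 1 - 1/k`, so
#'     `v(k+1)` equals the plain mean of all squared gradients and the
#'     method behaves asymptotically like SGD (the property the framework's
#'     bias analysis relies on). No bias correction is applied to `v` (an
#'     exact average needs none); avg_adam still bias-corrects `m`.}
#' }
#'
#' The EMA rates are `alpha = 0.9` (first moment) and `beta = 0.999`
#' (second moment), with stabilizer `eps = 1e-8` added outside the square
#' root. The step counter starts at `k = 1`, so for the averaged variants
#' `beta_1 = 0` and the first squared gradient overwrites `v`.
#'
#' @param method One of `"sgd"`, `"rmsprop"`, `"adam"`, `"avg_rmsprop"`,
#'   `"avg_adam"`.
#' @param m Flat parameter length.
#' @param alpha,beta EMA rates for the first and second moments.
#' @param eps Stabilizer.
#' @return `optimizer_state()` returns an object of class
#'   `"optimizer_state"` holding the step counter `k`, the accumulators `m`
#'   and `v`, and the hyperparameters.
#' @export
optimizer_state <- function(method = c("avg_adam", "sgd", "rmsprop", "adam",
                                       "avg_rmsprop"),
                            m, alpha = 0.9, beta = 0.999, eps = 1e-8) {
  method <- match.arg(method)
  structure(list(method = method, k = 1L,
                 m = rep(0, m), v = rep(0, m),
                 alpha = alpha, beta = beta, eps = eps),
            class = "optimizer_state")
}

#' @rdname optimizer_state
#' @param state An `"optimizer_state"`.
#' @param lambda Current flat parameter vector.
#' @param g Stochastic gradient estimate.
#' @param gamma Learning rate (`> 0`).
#' @return `opt_step()` returns `list(state = <updated state>,
#'   lambda = <updated parameters>)`.
#' @export
opt_step <- function(state, lambda, g, gamma) {
  stopifnot(gamma > 0, length(g) == length(lambda))
  k <- state$k
  d <- switch(state$method,
    sgd = g,
    rmsprop = {
      state$v <- state$beta * state$v + (1 - state$beta) * g * g
      g / (sqrt(state$v) + state$eps)
    },
    adam = {
      state$m <- state$alpha * state$m + (1 - state$alpha) * g
      state$v <- state$beta * state$v + (1 - state$beta) * g * g
      mhat <- state$m / (1 - state$alpha^k)
      vhat <- state$v / (1 - state$beta^k)
      mhat / (sqrt(vhat) + state$eps)
    },
    avg_rmsprop = {
      bk <- 1 - 1 / k
      state$v <- bk * state$v + (1 - bk) * g * g
      g / (sqrt(state$v) + state$eps)
    },
    avg_adam = {
      bk <- 1 - 1 / k
      state$m <- state$alpha * state$m + (1 - state$alpha) * g
      state$v <- bk * state$v + (1 - bk) * g * g
      mhat <- state$m / (1 - state$alpha^k)
      mhat / (sqrt(state$v) + state$eps)
    })
  lambda_new <- lambda - gamma * d
  if (any(!is.finite(lambda_new))) {
    bad <- which(!is.finite(lambda_new))[1]
    stop("non-finite optimizer update at coordinate ", bad,
         " (step ", k, ", method ", state$method, ")")
  }
  state$k <- k + 1L
  list(state = state, lambda = lambda_new)
}

#' @rdname optimizer_state
#' @export
optimizer_methods <- function() {
  c("sgd", "rmsprop", "adam", "avg_rmsprop", "avg_adam")
}
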