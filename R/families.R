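#' Mean-field Gaussian parameters
#'
#' The mean-field Gaussian family parameterizes a diagonal-covariance
#' Gaussian by a location vector `tau` and a log-scale vector `psi`, so
#' `q_lambda = N(tau, diag(exp(2 psi)))` with `lambda = (tau, psi)` of length
#' `m = 2d`. The flat-vector layout is always location first, then
#' log-scale; this ordering is the canonical trace layout used by all
#' diagnostics.
#'
#' @param loc Location vector `tau` (length `d`).
#' @param log_scale Log-scale vector `psi` (length `d`).
#' @return Object of class `"mf_params"` with fields `loc`, `log_scale` and
#'   the derived `scale = exp(log_scale)`.
#' @export
mf_params <- function(loc, log_scale) {
  stopifnot(length(loc) == length(log_scale),
            all(is.finite(loc)), all(is.finite(log_scale)))
  structure(list(loc = as.numeric(loc),
                 log_scale = as.numeric(log_scale),
                 scale = exp(as.numeric(log_scale))),
            class = "mf_params")
}

#' @rdname mf_params
#' @param params An `"mf_params"` object.
#' @export
mf_as_vector <- function(params) c(params$loc, params$log_scale)

#' @rdname mf_params
#' @param lambda Flat parameter vector of length `2d`, layout (loc, log_scale).
#' @export
mf_from_vector <- function(lambda) {
  stopifnot(length(lambda) %% 2 == 0)
  d <- length(lambda) / 2
  mf_params(lambda[seq_len(d)], lambda[d + seq_len(d)])
}

#' Family specification
#'
#' Lightweight descriptor of a variational family: its kind, dimension and
#' flat parameter count. The framework's termination machinery requires a
#' closed-form symmetrized KL between family members, which restricts the
#' supported kinds to Gaussians.
#'
#' @param kind `"mean_field_gaussian"` or `"full_rank_gaussian"`.
#' @param d Dimension of the target.
#' @return Object of class `"family_spec"` with fields `kind`, `dim`,
#'   `n_params` (`2d` mean-field, `d + d(d+1)/2` full-rank) and
#'   `closed_form_skl` (always `TRUE` for the supported kinds).
#' @export
family_spec <- function(kind = c("mean_field_gaussian", "full_rank_gaussian"), d) {
  kind <- match.arg(kind)
  stopifnot(d >= 1)
  m <- if (kind == "mean_field_gaussian") 2L * d else d + d * (d + 1L) / 2L
  structure(list(kind = kind, dim = as.integer(d), n_params = as.integer(m),
                 closed_form_skl = TRUE),
            class = "family_spec")
}

#' Sample from a mean-field Gaussian by reparameterization
#'
#' Deterministic given the standard-normal noise: row `i` of the output is
#' `loc + exp(log_scale) * noise[i, ]`.
#'
#' @param params An `"mf_params"` object.
#' @param n_draws Number of draws.
#' @param noise Optional `n_draws x d` matrix of standard-normal draws; drawn
#'   from the session RNG when `NULL`.
#' @return `n_draws x d` matrix of draws.
#' @export
mf_sample <- function(params, n_draws, noise = NULL) {
  d <- length(params$loc)
  if (is.null(noise)) {
    noise <- matrix(stats::rnorm(n_draws * d), n_draws, d)
  } else {
    if (!is.matrix(noise) || nrow(noise) != n_draws || ncol(noise) != d)
      stop("noise must be an n_draws x d matrix")
  }
  sweep(noise, 2, params$scale, "*") + rep(params$loc, each = n_draws)
}

#' Mean-field Gaussian log-density
#'
#' @param params An `"mf_params"` object.
#' @param theta A point (length `d`) or an `n x d` matrix of row-points.
#' @return Log-density value(s).
#' @export
mf_log_q <- function(params, theta) {
  d <- length(params$loc)
  theta <- matrix_points(theta, d)
  z <- sweep(sweep(theta, 2, params$loc, "-"), 2, params$scale, "/")
  -0.5 * rowSums(z^2) - sum(params$log_scale) - 0.5 * d * log(2 * pi)
}

#' Mean-field Gaussian entropy
#'
#' `H(q) = sum(psi) + (d/2)(1 + log 2 pi)`.
#'
#' @param params An `"mf_params"` object.
#' @return Entropy (nats).
#' @export
mf_entropy <- function(params) {
  d <- length(params$loc)
  sum(params$log_scale) + 0.5 * d * (1 + log(2 * pi))
}

# KL(q1 | q2) between diagonal Gaussians, closed form.
mf_kl <- function(p1, p2) {
  sum(p2$log_scale - p1$log_scale +
        (p1$scale^2 + (p1$loc - p2$loc)^2) / (2 * p2$scale^2) - 0.5)
}

#' Symmetrized KL divergence between mean-field Gaussians
#'
#' `SKL(q1, q2) = KL(q1 | q2) + KL(q2 | q1)`, via the closed-form Gaussian
#' KL in both directions. Symmetric, nonnegative, and zero iff the
#' parameters coincide.
#'
#' @param p1,p2 `"mf_params"` objects of the same dimension.
#' @return The symmetrized KL divergence (nats).
#' @export
mf_skl <- function(p1, p2) {
  if (length(p1$loc) != length(p2$loc)) stop("dimension mismatch")
  mf_kl(p1, p2) + mf_kl(p2, p1)
}

# ---- full-rank Gaussian (same contract; not on the optimization path) ----

#' Full-rank Gaussian parameters
#'
#' Parameterized by a location vector and a lower-triangular Cholesky factor
#' `L` of the covariance (`Sigma = L L'`), with strictly positive diagonal.
#' Provided behind the same contract as the mean-field family (sampling,
#' log-density, entropy, closed-form SKL); the optimization driver itself
#' supports only the mean-field family.
#'
#' @param loc Location vector.
#' @param chol_cov Lower-triangular Cholesky factor of the covariance.
#' @return Object of class `"fr_params"`.
#' @export
fr_params <- function(loc, chol_cov) {
  chol_cov <- as.matrix(chol_cov)
  d <- length(loc)
  stopifnot(nrow(chol_cov) == d, ncol(chol_cov) == d,
            all(diag(chol_cov) > 0),
            all(chol_cov[upper.tri(chol_cov)] == 0))
  structure(list(loc = as.numeric(loc), chol_cov = chol_cov),
            class = "fr_params")
}

#' @rdname fr_params
#' @param params An `"fr_params"` object.
#' @param n_draws Number of draws.
#' @param noise Optional `n_draws x d` standard-normal matrix.
#' @export
fr_sample <- function(params, n_draws, noise = NULL) {
  d <- length(params$loc)
  if (is.null(noise)) noise <- matrix(stats::rnorm(n_draws * d), n_draws, d)
  noise %*% t(params$chol_cov) + rep(params$loc, each = n_draws)
}

#' @rdname fr_params
#' @param theta A point or matrix of row-points.
#' @export
fr_log_q <- function(params, theta) {
  d <- length(params$loc)
  theta <- matrix_points(theta, d)
  z <- forwardsolve(params$chol_cov, t(sweep(theta, 2, params$loc, "-")))
  -0.5 * colSums(z^2) - sum(log(diag(params$chol_cov))) - 0.5 * d * log(2 * pi)
}

# KL(p1 | p2) between full-rank Gaussians.
fr_kl <- function(p1, p2) {
  d <- length(p1$loc)
  L1 <- p1$chol_cov; L2 <- p2$chol_cov
  M <- forwardsolve(L2, L1)                 # L2^{-1} L1
  dm <- forwardsolve(L2, p1$loc - p2$loc)
  0.5 * (sum(M^2) + sum(dm^2) - d) + sum(log(diag(L2))) - sum(log(diag(L1)))
}

#' Symmetrized KL between full-rank Gaussians
#'
#' Reduces exactly to [mf_skl()] when both Cholesky factors are diagonal.
#'
#' @param p1,p2 `"fr_params"` objects of the same dimension.
#' @return The symmetrized KL divergence (nats).
#' @export
fr_skl <- function(p1, p2) {
  if (length(p1$loc) != length(p2$loc)) stop("dimension mismatch")
  fr_kl(p1, p2) + fr_kl(p2, p1)
}
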