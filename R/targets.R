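#' Target distributions
#'
#' A target distribution is the (possibly unnormalized) posterior that the
#' variational approximation is fitted to. It is represented as a list with
#' class `"target_distribution"` holding the dimension, the unnormalized
#' log-density, its gradient, and (optionally) closed-form moments.
#'
#' Both `log_density_unnorm` and `grad_log_density` are vectorized over
#' points: they accept an `n x d` matrix of row-vectors and return,
#' respectively, a length-`n` vector and an `n x d` matrix.
#'
#' @name target_distribution
NULL

#' Construct a user-supplied target distribution
#'
#' @param dim Positive integer dimension `d`.
#' @param log_density_unnorm Function mapping an `n x d` matrix to a length-`n`
#'   vector of unnormalized log-density values. The additive normalization
#'   constant is arbitrary; everything downstream is invariant to it.
#' @param grad_log_density Optional function mapping an `n x d` matrix to the
#'   `n x d` matrix of gradients. If `NULL`, a central finite-difference
#'   fallback with step `1e-6 * (1 + |theta_i|)` is used (slow; a warning is
#'   emitted once at construction).
#' @param mean,cov Optional closed-form moments (length-`d` vector and
#'   `d x d` symmetric positive-definite matrix).
#' @return An object of class `"target_distribution"`.
#' @export
new_target <- function(dim, log_density_unnorm, grad_log_density = NULL,
                       mean = NULL, cov = NULL) {
  stopifnot(is.numeric(dim), length(dim) == 1L, dim >= 1, dim == round(dim))
  d <- as.integer(dim)
  if (is.null(grad_log_density)) {
    warning("no gradient supplied; falling back to central finite differences ",
            "(slow path)", call. = FALSE)
    grad_log_density <- make_fd_gradient(log_density_unnorm, d)
  }
  if (!is.null(cov)) {
    cov <- as.matrix(cov)
    stopifnot(nrow(cov) == d, ncol(cov) == d)
    if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
      stop("covariance must be symmetric")
    ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("covariance must be positive definite")
  }
  structure(list(dim = d,
                 log_density_unnorm = log_density_unnorm,
                 grad_log_density = grad_log_density,
                 mean = mean, cov = cov),
            class = "target_distribution")
}

# Central finite differences, step 1e-6 * (1 + |theta_i|).
make_fd_gradient <- function(logp, d) {
  force(logp); force(d)
  function(theta) {
    theta <- matrix_points(theta, d)
    g <- matrix(NA_real_, nrow(theta), d)
    for (i in seq_len(d)) {
      h <- 1e-6 * (1 + abs(theta[, i]))
      up <- theta; up[, i] <- up[, i] + h
      dn <- theta; dn[, i] <- dn[, i] - h
      g[, i] <- (logp(up) - logp(dn)) / (2 * h)
    }
    g
  }
}

# Coerce a single point or a matrix of row-points to n x d.
matrix_points <- function(theta, d) {
  if (is.matrix(theta)) {
    stopifnot(ncol(theta) == d)
    theta
  } else {
    stopifnot(length(theta) == d)
    matrix(theta, nrow = 1L)
  }
}

#' Synthetic Gaussian target suite
#'
#' Zero-mean Gaussian targets `N(0, V)` whose covariance structures span
#' condition numbers from 1 to around 9000, used to benchmark the optimizer
#' against the analytically known optimal mean-field approximation.
#'
#' Available structures (entries of `V`, with `1[.]` the indicator):
#' \describe{
#'   \item{identity}{`V = I`.}
#'   \item{diag}{`V_ij = j 1[i=j]` (diagonal, non-identity).}
#'   \item{uniform}{`V_ij = 1[i=j] + 0.8 1[i!=j]`.}
#'   \item{banded}{`V_ij = 1[i=j] + 0.8^|i-j| 1[i!=j]`.}
#'   \item{diag_banded}{`V_ij = j 1[i=j] + 0.8^|i-j| 1[i!=j]`.}
#'   \item{spike_uniform}{`V_ij = 1000 1[i=j=1] + 1[i=j!=1] + 0.8 1[i!=j]`.}
#'   \item{spike_banded}{`V_ij = 1000 1[i=j=1] + 1[i=j!=1] + 0.8^|i-j| 1[i!=j]`.}
#' }
#'
#' @param structure_tag One of the seven structure names above.
#' @param d Positive integer dimension (default 100).
#' @return An object of classes `"gaussian_target"` and
#'   `"target_distribution"`, with precomputed `cov_inv` for fast gradient
#'   evaluation and the `structure_tag` recorded.
#' @examples
#' tgt <- make_gaussian_target("banded", 3)
#' tgt$cov[1, 3]  # 0.8^2
#' @export
make_gaussian_target <- function(structure_tag, d = 100L) {
  tags <- c("identity", "diag", "uniform", "banded", "diag_banded",
            "spike_uniform", "spike_banded")
  structure_tag <- match.arg(structure_tag, tags)
  stopifnot(is.numeric(d), length(d) == 1L, d >= 1, d == round(d))
  d <- as.integer(d)
  idx <- seq_len(d)
  band <- 0.8^abs(outer(idx, idx, "-"))
  V <- switch(structure_tag,
    identity      = diag(1, d),
    diag          = diag(as.numeric(idx), d),
    uniform       = matrix(0.8, d, d) + diag(0.2, d),
    banded        = band,
    diag_banded   = band - diag(1, d) + diag(as.numeric(idx), d),
    spike_uniform = { M <- matrix(0.8, d, d) + diag(0.2, d); M[1, 1] <- 1000; M },
    spike_banded  = { M <- band; M[1, 1] <- 1000; M }
  )
  mean <- rep(0, d)
  Vinv <- chol2inv(chol(V))
  logp <- function(theta) {
    theta <- matrix_points(theta, d)
    -0.5 * rowSums((theta %*% Vinv) * theta)
  }
  grad <- function(theta) {
    theta <- matrix_points(theta, d)
    -theta %*% Vinv
  }
  structure(list(dim = d,
                 log_density_unnorm = logp,
                 grad_log_density = grad,
                 mean = mean, cov = V, cov_inv = Vinv,
                 structure_tag = structure_tag),
            class = c("gaussian_target", "target_distribution"))
}

#' Resolve a target from a string key
#'
#' Keys have the form `"gaussian:<structure>:d=<dim>"`, e.g.
#' `"gaussian:diag:d=100"`. The dimension component is optional and defaults
#' to 100.
#'
#' @param key Target key string.
#' @return A `"target_distribution"` object.
#' @export
resolve_target <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2L || parts[1] != "gaussian")
    stop("unknown target key: ", key,
         " (expected \"gaussian:<structure>[:d=<dim>]\")")
  tag <- parts[2]
  d <- 100L
  if (length(parts) >= 3L) {
    m <- regmatches(parts[3], regexec("^d=([0-9]+)$", parts[3]))[[1]]
    if (length(m) != 2L) stop("bad dimension component in target key: ", key)
    d <- as.integer(m[2])
  }
  make_gaussian_target(tag, d)
}

#' Optimal mean-field Gaussian approximation of a Gaussian target
#'
#' For a Gaussian target `N(m, V)` the KL(q | pi)-minimizing mean-field
#' Gaussian has location `m` and scales `sigma_i = ((V^{-1})_{ii})^{-1/2}`
#' (diagonal precision matching).
#'
#' @param target A `"gaussian_target"` (moments must be present).
#' @return A [mf_params()] object.
#' @export
optimal_mean_field <- function(target) {
  if (is.null(target$cov)) stop("target has no closed-form moments")
  Vinv <- target$cov_inv %||% chol2inv(chol(target$cov))
  mf_params(loc = target$mean, log_scale = -0.5 * log(diag(Vinv)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exponential-control scale constant
#'
#' Computes the minimal `c > 0` such that the target is exponentially
#' controlled at order `p` with scale matrix `c^2 V`: the log of the
#' moment-type integral `E[exp(||(c^2 V)^{-1/2}(theta - theta')||_2^p)]`,
#' minimized over centres `theta'`, is at most `d/2`. For a Gaussian target
#' the centre minimum is at the mean (symmetry) and the integrand reduces to
#' a function of `||z||^2 ~ chi^2_d`; with `p = 2` the integral is available
#' in closed form, `-(d/2) log(1 - 2/c^2)` for `c^2 > 2`, so the minimal
#' constant is `sqrt(2 / (1 - exp(-1)))`, independent of `d`.
#'
#' @param target A `"gaussian_target"`.
#' @param p Order of the control condition, `p >= 1` (default 2).
#' @param tol Bisection tolerance on `c` (default 1e-6).
#' @return The minimal admissible scale factor `c`.
#' @export
exponential_control_scale <- function(target, p = 2, tol = 1e-6) {
  stopifnot(p >= 1)
  d <- target$dim
  # log E[exp((||z||/c)^p)] - d/2, z ~ N(0, I_d); admissible iff <= 0
  crit <- function(cc) {
    if (p == 2) {
      if (cc^2 <= 2) return(Inf)
      -(d / 2) * log(1 - 2 / cc^2) - d / 2
    } else {
      # quadrature over s = ||z||^2 ~ chi^2_d, stabilized by factoring out
      # the value at the chi^2 mean
      f <- function(s) exp((sqrt(s) / cc)^p + stats::dchisq(s, df = d, log = TRUE))
      val <- tryCatch(
        stats::integrate(f, 0, Inf, rel.tol = 1e-10, abs.tol = 0)$value,
        error = function(e) Inf)
      if (!is.finite(val) || val <= 0) return(Inf)
      log(val) - d / 2
    }
  }
  lo <- sqrt(2) * (1 + 1e-9)
  hi <- 100
  if (crit(hi) > 0) stop("control integral diverges over the search range")
  if (crit(lo) <= 0) return(lo)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (crit(mid) <= 0) hi <- mid else lo <- mid
  }
  hi
}

#' Relative accuracy metrics
#'
#' Scale-aware errors of an approximate mean/sd against a reference:
#' `rel_mean_err = ||(ref_mean - approx_mean) / ref_sd||_2` and
#' `rel_sd_err = ||approx_sd / ref_sd - 1||_2` (elementwise division).
#'
#' @param approx_mean,approx_sd Approximation mean and sd vectors.
#' @param ref_mean,ref_sd Reference mean and sd vectors (`ref_sd > 0`).
#' @return List with `rel_mean_err` and `rel_sd_err`.
#' @export
accuracy_metrics <- function(approx_mean, approx_sd, ref_mean, ref_sd) {
  stopifnot(length(approx_mean) == length(ref_mean),
            length(approx_sd) == length(ref_sd),
            length(approx_mean) == length(approx_sd))
  if (any(ref_sd <= 0)) stop("reference sd must be positive elementwise")
  list(rel_mean_err = sqrt(sum(((ref_mean - approx_mean) / ref_sd)^2)),
       rel_sd_err   = sqrt(sum((approx_sd / ref_sd - 1)^2)))
}
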