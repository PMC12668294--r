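#' Split-R-hat of a single chain
#'
#' Potential scale reduction factor computed by splitting one chain into two
#' halves (dropping the middle element when the length is odd):
#' `Rhat = sqrt(Vhat / What)` where `What` is the mean within-half variance
#' and `Vhat = (n-1)/n * What + B/n` with `B` the between-half variance.
#' Values near 1 indicate the window is consistent with stationarity.
#'
#' Degenerate cases: when the within-half variance is exactly zero but the
#' halves differ, `+Inf` is returned; an all-constant input returns `NaN`
#' with a warning.
#'
#' @param x Numeric vector (the trailing window of one coordinate's chain).
#' @return The split-R-hat value.
#' @export
split_rhat <- function(x) {
  W <- length(x)
  if (W < 4) stop("window length must be at least 4")
  n <- W %/% 2L
  h1 <- x[seq_len(n)]
  h2 <- x[seq.int(W - n + 1L, W)]
  m1 <- mean(h1); m2 <- mean(h2)
  s1 <- stats::var(h1); s2 <- stats::var(h2)
  What <- (s1 + s2) / 2
  B <- n * (m1 - m2)^2 / 2          # n * var of the two half-means
  if (What == 0) {
    if (B > 0) return(Inf)
    warning("all-constant chain window; split-R-hat undefined")
    return(NaN)
  }
  sqrt(((n - 1) / n * What + B / n) / What)
}

#' Maximum split-R-hat over coordinates
#'
#' Evaluates [split_rhat()] on the trailing `W` iterates of every coordinate
#' of an iterate trace and returns the maximum (the stationarity statistic:
#' the chain is only declared stationary when its worst coordinate looks
#' stationary).
#'
#' @param trace `k x m` matrix of iterates (rows are iterations).
#' @param W Window size, `4 <= W <= nrow(trace)`.
#' @return Maximum split-R-hat; `NaN` components are ignored unless all are
#'   `NaN`.
#' @export
rhat_max <- function(trace, W) {
  k <- nrow(trace)
  stopifnot(W <= k)
  rows <- seq.int(k - W + 1L, k)
  vals <- suppressWarnings(apply(trace[rows, , drop = FALSE], 2, split_rhat))
  if (all(is.nan(vals))) return(NaN)
  max(vals, na.rm = TRUE)
}

#' Adaptive window search for the stationarity check
#'
#' Evaluates [rhat_max()] at 5 equally spaced window sizes from `Wmin` to
#' `floor(0.95 k)` (rounded to the nearest integer, duplicates removed) and
#' returns the window minimizing the statistic. Ties are broken toward the
#' larger window, which maximizes the data available for iterate averaging.
#' The 0.95 ceiling always allows a little warm-up to be discarded without
#' sacrificing more than 5% of the chain.
#'
#' @param trace `k x m` iterate matrix.
#' @param Wmin Minimum window size (the split-R-hat values are unreliable on
#'   very short windows).
#' @return List with `Wopt`, `rhat` (the statistic at `Wopt`), and the
#'   candidate `grid`.
#' @export
find_opt_window <- function(trace, Wmin) {
  k <- nrow(trace)
  Wmax <- floor(0.95 * k)
  if (Wmax < Wmin) stop("trace too short: floor(0.95 k) < Wmin")
  grid <- unique(round(seq(Wmin, Wmax, length.out = 5L)))
  vals <- vapply(grid, function(W) rhat_max(trace, W), numeric(1))
  ok <- !is.nan(vals)
  if (!any(ok)) return(list(Wopt = max(grid), rhat = NaN, grid = grid))
  grid2 <- grid[ok]; vals2 <- vals[ok]
  best <- max(grid2[vals2 <= min(vals2)])    # tie-break toward larger window
  list(Wopt = best, rhat = vals2[match(best, grid2)], grid = grid)
}

# Autocovariance function (biased, lags 0..n-1) via FFT.
autocov_fft <- function(y) {
  n <- length(y)
  y <- y - mean(y)
  npad <- stats::nextn(2L * n)
  f <- stats::fft(c(y, rep(0, npad - n)))
  Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] /
    (as.double(npad) * n)
}

#' Effective sample size of a single chain
#'
#' FFT-based autocovariance estimator on the split chain (two halves), with
#' Geyer's initial monotone positive-sequence truncation of the paired
#' autocorrelations. No upper cap is applied to the raw estimate. A constant
#' chain returns `length(x)` by convention.
#'
#' @param x Numeric vector, length at least 8.
#' @return Estimated effective sample size.
#' @export
ess <- function(x) {
  N <- length(x)
  if (N < 8) stop("chain too short for ESS estimation (need >= 8)")
  if (stats::var(x) == 0) return(as.numeric(N))
  n <- N %/% 2L
  chains <- list(x[seq_len(n)], x[seq.int(N - n + 1L, N)])
  acov <- vapply(chains, autocov_fft, numeric(n))   # n x 2, biased /n
  chain_vars <- acov[1L, ] * n / (n - 1)
  mean_var <- mean(chain_vars)                      # within-chain variance W
  var_plus <- mean_var * (n - 1) / n + stats::var(c(mean(chains[[1]]), mean(chains[[2]])))
  if (var_plus == 0) return(as.numeric(N))
  rho <- 1 - (mean_var - rowMeans(acov)) / var_plus # rho[1] is lag 0
  # Geyer pairs P_k = rho_{2k} + rho_{2k+1}, k = 0, 1, ...
  max_pairs <- n %/% 2L
  tau <- -1
  prev_pair <- Inf
  for (kk in seq_len(max_pairs)) {
    i <- 2L * (kk - 1L) + 1L
    pair <- rho[i] + if (i + 1L <= n) rho[i + 1L] else 0
    if (kk > 1L && pair < 0) break
    pair <- min(pair, prev_pair)   # initial monotone sequence
    prev_pair <- pair
    tau <- tau + 2 * pair
  }
  tau <- max(tau, 1 / log10(N + 1))  # guard against pathological negatives
  (2 * n) / tau
}

#' Monte Carlo standard error of a chain mean
#'
#' `MCSE = sd(x) / sqrt(ESS(x))`; zero for a constant chain.
#'
#' @param x Numeric vector, length at least 8.
#' @return Estimated Monte Carlo standard error.
#' @export
mcse <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(0)
  s / sqrt(ess(x))
}

# ESS for every column of a window; used by the averaging gate.
ess_by_col <- function(window) apply(window, 2, ess)

#' Per-window diagnostics table
#'
#' Summarizes an iterate window as a one-row data frame (iteration count,
#' worst-coordinate split-R-hat, minimum ESS, mean MCSEs), suitable for
#' accumulation into a delimited-text diagnostics log.
#'
#' @param window `k x m` iterate matrix.
#' @param Wmin Minimum window size for the R-hat search.
#' @return One-row `data.frame`.
#' @export
diagnostics_table <- function(window, Wmin = 200L) {
  k <- nrow(window)
  rh <- if (floor(0.95 * k) >= Wmin) find_opt_window(window, Wmin)$rhat else NA_real_
  es <- ess_by_col(window)
  mc <- apply(window, 2, mcse)
  data.frame(iterations = k, rhat_max = rh,
             ess_min = min(es), mcse_mean = mean(mc))
}
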