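---
title: "Methods: automated stochastic optimization for black-box variational inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated stochastic optimization for black-box variational inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Black-box variational inference (BBVI) approximates a posterior
$\pi \propto \pi_u$ by the member $q_{\lambda^*}$ of a tractable family
$\mathcal{Q} = \{q_\lambda\}$ minimizing $\mathrm{KL}(q_\lambda \mid \pi)$,
using only evaluations of $\log \pi_u$ and its gradient. The optimization is
stochastic: at iteration $k$,
$\lambda^{(k+1)} \leftarrow \lambda^{(k)} - \gamma \, d^{(k)}$, with
$d^{(k)}$ built from an unbiased reparameterization-gradient estimate of the
KL objective. In practice this optimization is the unreliable part of BBVI:
the user must pick a learning-rate schedule, an iteration count, and a
stopping rule, and a poor choice silently yields an inaccurate
approximation. This package automates all three decisions.

The core family is the mean-field Gaussian,
$q_\lambda = \mathcal{N}(\tau, \operatorname{diag} e^{2\psi})$ with
$\lambda = (\tau, \psi) \in \mathbb{R}^{2d}$ (locations first, then
log-scales — this flat layout is used by every diagnostic and trace). The
log-scale parameterization is load-bearing: the averaging gate's guarantee
is stated in terms of perturbations of $\psi$, so no softplus alternative is
offered. A full-rank Gaussian is provided behind the same contract
(sampling, log-density, entropy, closed-form symmetrized KL) but is not on
the optimization path. Families without a closed-form symmetrized KL
(normalizing flows) are rejected at configuration time, because the
termination machinery is built on exact SKL evaluations between family
members.

## Fixed-learning-rate epochs and iterate averaging

With a fixed learning rate $\gamma$, the iterates form a homogeneous Markov
chain with stationary mean $\bar\lambda_\gamma$, which is an $O(\gamma)$-accurate
(for SGD-like dynamics) estimate of $\lambda^*$ — much better than the
$O(\gamma^{1/2})$ fluctuation of an individual iterate. Each epoch therefore
(1) detects when the chain has reached stationarity, then (2) accumulates a
Polyak–Ruppert iterate average
$\hat\lambda_\gamma = k_{\mathrm{avg}}^{-1}\sum_{k=0}^{k_{\mathrm{avg}}-1}
\lambda^{(k_{\mathrm{conv}}+k)}$ until it is demonstrably close to
$\bar\lambda_\gamma$.

**Stationarity detection.** Every $W_{\min}$ iterations the worst-coordinate
split-$\widehat{R}$ is minimized over 5 equally spaced window sizes between
$W_{\min}$ and $0.95k$; the chain is declared stationary when that minimum is
at most 1.1. We use the plain (not rank-normalized) split statistic: iterate
chains near stationarity are approximately Gaussian, and the cruder 1.1
threshold reflects that iterate averaging needs far less precision than
MCMC inference. The window grid is rounded with R's `round()`
(half-to-even), ties in the argmin go to the larger window (more data for
the average), and the $0.95k$ ceiling always discards a little warm-up. One
deliberate extension: a window in which *every* coordinate is exactly
constant (the split-$\widehat{R}$ sentinel `NaN`) is treated as stationary —
this is the fixed point of a noiseless chain, which would otherwise never be
detected.

**The averaging gate.** The average is accepted once, per coordinate group,
the mean scaled Monte Carlo standard errors
$d^{-1}\sum_i \mathrm{MCSE}(\tau_i)/\hat\sigma_i$ and
$d^{-1}\sum_i \mathrm{MCSE}(\psi_i)$ fall below $\varepsilon$ and every
coordinate's effective sample size is at least 50 (below that the MCSE
estimates themselves are untrustworthy). ESS uses an FFT autocovariance
estimator on the split chain with Geyer's initial monotone positive-sequence
truncation, with no upper cap; a constant chain has ESS equal to its length
by convention. The point of the gate is a quantitative guarantee: if
$|\hat\tau_i - \bar\tau_i| \le \varepsilon \hat\sigma_i$ and
$|\hat\psi_i - \bar\psi_i| \le \varepsilon$ with
$\varepsilon \in (0, 1/2]$, the relative scale error is at most
$1.5\,\varepsilon$ and the relative location error at most
$1.75\,\varepsilon$; the package verifies those two constants by dense grid
search (`worst_case_sd_error_factor()`, `worst_case_loc_error_factor()`,
whose exact suprema are $(e^{1/2}-1)/0.5 \approx 1.30$ and
$e^{1/2} \approx 1.65$).

**Check scheduling.** Each gate check costs ESS computations for all $2d$
coordinates, so checks happen at iterations
$k_{\mathrm{conv}} + \chi(r)^j W_{\mathrm{conv}}$ with
$\chi(r) = 1 + (1+r)^{-1/2}$, where $r$ is the ratio of per-iterate
optimization cost to per-iterate check cost, measured from wall time after
the first check (doubling, $\chi = 2$, until then). This costs at most a
factor $g(r) = (2 + r + 2\sqrt{1+r})/(1+r) \le 4$ more than checking at
exactly the right moment. Because $r$ is measured from wall time, the check
schedule (and hence $k_{\mathrm{avg}}$) is not bit-reproducible across runs;
passing `cost_ratio = 0` (or any fixed value) in the configuration restores
exact determinism, and the determinism tests do exactly that.

## Estimating the distance to the optimum

Let $q^*_\gamma := q_{\bar\lambda_\gamma}$. For the mean-field Gaussian
family with SGD-like dynamics the symmetrized KL between the optima at
successive learning rates obeys
$\delta_t := \mathrm{SKL}(q^*_{\gamma_t}, q^*_{\gamma_{t-1}})
\approx C \gamma_t^{2\kappa} (1/\rho^\kappa - 1)^2$ with $\kappa = 1$,
which extrapolates to
$\mathrm{SKL}(q^*_\gamma, q^*) \approx C\gamma^{2\kappa}$. Adaptive
optimizers break the $\kappa = 1$ behaviour, which motivates the *averaged*
variants avgRMSProp/avgAdam: the squared-gradient accumulator becomes a
plain running average ($\beta_k = 1 - 1/k$), so the preconditioner freezes
asymptotically and the SGD bias analysis applies again. avgAdam still keeps
the usual EMA (and bias correction) for the first moment — only the
second-moment update is modified. With other optimizers or families,
$\kappa$ is treated as unknown in $(0,1)$.

$C$ (and $\kappa$) are estimated from the regression
$\log \delta_t = \log C + 2\log(1/\rho^\kappa - 1) + 2\kappa \log\gamma_t +
\eta_t$, $\eta_t \sim \mathcal{N}(0, \sigma^2)$, with weak priors
$\log C \sim \mathrm{Cauchy}(0, 10)$, $\sigma \sim \mathrm{Cauchy}^+(0,10)$,
$\kappa \sim \mathrm{Unif}(0,1)$, and with each observation's log-likelihood
term *tempered* by the recency weight $w_t = \{1 + (T-t)^2/32\}^{-1/4}$
(early $\delta_t$ carry higher-order bias; the weight placement — tempering
rather than variance inflation — is a documented choice, as the model
statement leaves it open). The posterior is computed by deterministic
mode-region grid quadrature over $(\log C, \log\sigma)$, plus a fixed
$\kappa$ grid in the free-$\kappa$ mode, with range-refinement passes; no
MCMC is involved and the numerical error is orders of magnitude below the
2% the downstream rule tolerates. We report
$\hat{C} = \exp(\mathbb{E}[\log C])$: with one or two observations the
posterior of $\log C$ has heavy symmetric tails, making
$\mathbb{E}[C]$ tail-dominated and unstable while the geometric mean stays
centred; the two agree whenever the posterior concentrates.

## The termination rule

After each epoch the framework asks whether halving the learning rate again
is worth it. The predicted relative SKL improvement is
$\widehat{\mathrm{RSKL}} = \rho^{\hat\kappa} +
\xi / (\hat{C}^{1/2}\gamma_t^{\hat\kappa})$, where $\xi$ is the user's
accuracy target for $\sqrt{\mathrm{SKL}(q^*, \hat{q}^*)}$; the predicted
relative cost is $\widehat{\mathrm{RI}} =
\widehat{K}_{\gamma_{t+1}} / (K_{\gamma_t} + K_0)$, with
$\widehat{K}_{\gamma_{t+1}} = \gamma_{t+1}^{\hat\alpha} e^{\hat\beta}$ from
a weighted least-squares fit of $\log K_{\gamma_t}$ on $\log \gamma_t$
(same recency weights; all epochs with an iteration record are used,
including the first). Optimization stops when the inefficiency index
$\hat{\mathcal{I}} = \widehat{\mathrm{RSKL}} \times \widehat{\mathrm{RI}}$
exceeds $\tau$, which for $\xi = 0.1$ empirically happens when
$\sqrt{\mathrm{SKL}}$ to the optimum is close to 0.1.

The rule is evaluated once per epoch and only when enough $\delta_t$ exist
(2 in fixed-$\kappa$ mode, 3 in free mode). A structural consequence: the
rule cannot stop before the third epoch, so for large $\xi$ (or small
problems) the exit accuracy *overshoots* — the returned approximation is
better than requested, and "exit accuracy $\approx \xi$" can only hold from
above. This is visible in the tests: the factor-3 two-sided tracking band
is asserted only where it is structurally attainable.

Each new epoch runs at $\gamma_{t+1} = \rho\gamma_t$ and warm-starts from
$\hat\lambda_{\gamma_t}$ — the iterate average, not the last raw iterate,
since the average has far lower variance (an interpretation choice the
algorithm statement leaves open; the first iterate of each epoch is exactly
one optimizer step from the previous average). The gate threshold stays at
$\varepsilon_0$ across epochs by default; `eps_decay` exposes geometric
decay for users who read the "initial threshold" wording as decaying.

## Tunable parameters

| Parameter | Default | Meaning / why this value |
|---|---|---|
| $\xi$ | 0.1 | target for $\sqrt{\mathrm{SKL}}$ to the optimum; 0.01–1 when the family fits well, 1–10 otherwise |
| $\tau$ | 1 | inefficiency threshold; >1 favours accuracy, <1 favours compute |
| $K_{\max}$ | 100000 | global iteration budget; exhaustion warns and returns best effort |
| $\gamma_0$ | 0.3 | problem-independent for adaptive optimizers |
| $W_{\min}$ | 200 | each split-$\widehat{R}$ half then has $\ge$ 100 iterates |
| $K_0$ | $5W_{\min} = 1000$ | iteration count considered "small" in RI |
| $\varepsilon_0$ | $\xi$ | gate threshold scales with the accuracy goal |
| $\rho$ | 0.5 | smaller gives too few $\delta_t$; larger is too slow |
| $M$ | 10 | Monte Carlo draws per gradient; robust as long as not tiny |
| optimizer | avgAdam | $\varepsilon = 10^{-8}$ outside the square root; Adam rates $\alpha = 0.9$, $\beta = 0.999$ (standard values; the bias analysis does not pin them down) |

## What the synthetic suite does and does not establish

The seven zero-mean Gaussian targets (identity, diagonal, uniform 0.8,
banded $0.8^{|i-j|}$, their diagonal combinations, and two spiked variants
with $V_{11} = 1000$) span condition numbers from 1 to roughly 9000 and have
*analytically known* optimal mean-field approximations
($\tau^* = 0$, $\sigma_i^* = ((V^{-1})_{ii})^{-1/2}$), so every accuracy
claim in the tests is against exact ground truth. Default dimension is 100,
configurable. Gaussian targets make the reparameterized objective exactly
quadratic-in-location and give log-concave, symmetric, light-tailed
geometry; a green suite therefore establishes the correctness of the
optimization, diagnostics, regression and termination machinery, but says
nothing about multimodality, heavy tails, strong nonconvexity, or
funnel-like geometry in real posteriors. User targets enter through the same
contract (`new_target()`), including a finite-difference gradient fallback
(step $10^{-6}(1+|\theta_i|)$, warned, slow).

## Numerical choices and degenerate inputs

- Targets are defined up to an additive constant; every downstream quantity
  is invariant to it (tested by shifting the log-density by 7.3).
- The exponential-control scale (the constant fixing the scale matrix at
  which KL controls Wasserstein distance) is found by bisection on
  $c \in [\sqrt{2}(1+10^{-9}), 100]$ to $10^{-6}$; for Gaussian targets the
  centre infimum is at the mean by symmetry, the $p = 2$ integral is the
  closed form $-(d/2)\log(1 - 2/c^2)$, other $p$ use quadrature against the
  $\chi^2_d$ density. The minimal constant for $p = 2$ is
  $\sqrt{2/(1-e^{-1})} \approx 1.78$, independent of $d$.
- Non-finite target log-density at a draw: redraw up to 10 times, then fail
  with the offending location. Non-finite optimizer update: one retry from
  the last finite iterate with fresh noise, then fail with epoch context.
- $\delta_t \le 0$ cannot occur in exact arithmetic (SKL $\ge 0$, and
  successive averages never coincide in floating point); if supplied
  directly to the regression, such observations are dropped with a warning.
- All randomness derives from the configured seed; each epoch records its
  own derived seed so any epoch is replayable in isolation.

## Known limitations

- Only the mean-field Gaussian family is optimizable; full-rank support is
  limited to the family contract (no gradients/driver path).
- Single-chain diagnostics only ($J = 1$, split in two); no
  rank-normalized or folded $\widehat{R}$ variants.
- The measured-cost check schedule trades exact reproducibility for
  efficiency unless `cost_ratio` is fixed.
- The iteration-prediction power law assumes smooth growth of convergence
  times across epochs; abrupt regime changes (e.g. an epoch that hits the
  global budget) degrade $\widehat{\mathrm{RI}}$ and hence the termination
  point, though never the validity of the returned average itself.
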