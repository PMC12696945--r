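---
title: "Federated GAMLSS: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated GAMLSS: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains what `fedgamlss` computes, the assumptions behind it,
and the design choices made where several implementations would have been
defensible. It states no empirical result that the package's tests and
acceptance script do not themselves compute.

## The model

A GAMLSS assumes a parametric response distribution whose parameters
θ = (μ, σ, ν, τ) each follow an additive predictor through a monotone link:

$$g_k(\theta_k) = \eta_k = X_k\beta_k + \sum_j Z_{kj}\gamma_{kj},$$

with linear design matrices $X_k$ and P-spline bases $Z_{kj}$ penalized by
$\lambda_{kj}\gamma'G\gamma$, $G = D'D$ the difference penalty. Estimation
maximizes the penalized log-likelihood

$$l_p = \sum_i \log f(y_i\mid\theta_i) -
\tfrac12\sum_k\sum_j \lambda_{kj}\,\gamma_{kj}' G_{kj}\gamma_{kj}.$$

Three families are provided.

* **NO** — normal with identity-link mean and log-link standard deviation.
* **BCCG** — Box–Cox Cole–Green for positive, skewed responses: with
  $z = ((y/\mu)^\nu - 1)/(\sigma\nu)$ ($\log(y/\mu)/\sigma$ at $\nu = 0$),
  $z$ is standard normal truncated below $-1/(\sigma|\nu|)$. μ is (very
  nearly) the median, σ the coefficient of variation, ν the skewness
  (Box–Cox) power.
* **BCPE** — replaces the normal kernel by a standardized power exponential
  with kurtosis parameter τ; τ = 2 recovers BCCG exactly, which the tests
  exploit as a nesting oracle since the two families are implemented with
  different kernels (`qnorm`/`pnorm` versus incomplete-gamma forms).

The truncation constant $F_Z(1/(\sigma|\nu|))$ is included in the density
(so densities integrate to one exactly, which is asserted by quadrature in
the tests), in the CDF, and in the quantile function, which inverts the full
truncated CDF in closed form through the gamma quantile function. Scores on
the predictor scale are analytic, including the truncation-constant
derivatives with respect to σ and ν; the derivative of the constant with
respect to τ has no closed form and is obtained by an accurate central
difference on that scalar alone. A finite-difference oracle verifies all
scores to 1e-5 relative error on randomized valid parameters.

**Iterative weights.** The normal family uses expected information (1/σ²
for μ, the constant 2 for log σ), BCCG uses the known expected-information
forms for μ and σ, and all remaining parameters — BCCG ν and everything in
BCPE — use quasi-Newton squared-score weights, the convention of the
reference family implementations. Weights are floored at 1e-10 and σ, τ, and
the Box–Cox μ are clipped at 1e-8 because RS iterations can transiently
produce extreme predictors.

## The RS algorithm

Fitting cycles three nested loops until the global deviance (−2 log
likelihood) stabilizes:

1. **Outer** over distribution parameters (deviance change < `outer_tol`,
   default 1e-3 absolute, at most 50 cycles);
2. **Inner** per parameter: compute score u and weight w at the current
   state, form the working response z = η + u/w, refit, repeat while the
   deviance moves more than `inner_tol` (1e-3, at most 10 iterations);
3. **Backfitting** over additive terms: the linear part and then each smooth
   are fitted to their partial residuals by penalized weighted least
   squares, cycling until the predictor changes by less than `backfit_tol`
   (1e-6, at most 30 cycles).

**Initialization** is coefficient-based: every parameter starts at a
constant (its link applied to a moment-based starting value — the response
mean and SD for NO; the mean, coefficient of variation, ν = 1, τ = 2 for the
Box–Cox families). A per-observation shrunken start is common elsewhere, but
a constant start keeps the predictor inside the span of the design at all
times, which makes two things exact: coefficient-space step control and
model serialization. On the simulated study conditions the constant start
costs a few extra inner iterations at most.

**Step control.** A proposed update for one parameter is accepted only if
the penalized deviance (evaluated at the current smoothing parameters) does
not increase; otherwise the new coefficients are halved toward the previous
ones, up to 10 times, and as a last resort the previous iterate is kept with
a warning. With fixed smoothing parameters this makes the penalized-deviance
trace provably non-increasing (a tested invariant). When λ is being
estimated the objective itself moves between steps, so monotonicity is only
enforced conditionally on the current λ.

**Linear algebra.** Every term update solves
$(C'WC + \lambda G)b = C'Wz$ from aggregated cross-products via a dense
solve, verified in the tests against an explicit brute-force normal-equations
oracle at 1e-10. An exactly singular system is an error naming the collinear
columns (found by pivoted QR). Deliberately, a merely ill-conditioned system
is *not* an error: the λ → ∞ ridge limit, which the tests exercise at
λ = 1e12, is ill-conditioned by construction yet solves accurately because
the null-space block remains well conditioned.

## Smoothing-parameter estimation

Each `pb()` term's λ is estimated locally inside backfitting by the
variance-ratio fixed point: with $H = Z'WZ + \lambda G$,
$\mathrm{edf} = \mathrm{tr}(H^{-1}Z'WZ)$,

$$\lambda \leftarrow \frac{\hat\sigma_e^2}{\hat\sigma_b^2}
  = \frac{\text{wRSS}/(n-\mathrm{edf})}{\gamma'G\gamma/(\mathrm{edf}-d)},$$

iterated to relative tolerance 1e-3 (at most 30 sub-iterations) and clamped
to [1e-7, 1e7], where d is the penalty order. The tests compare the fixed
point against an independent 50-point grid search of the profile restricted
likelihood and require agreement within a factor of two (observed: a few
percent).

Two safeguards matter in practice, both discovered by seed sweeps during
development. First, at very large λ the effective degrees of freedom equal
the null-space dimension, which makes the naive ratio degenerate and λ
absorbing at its cap; the denominator is therefore floored so the iteration
can move back down. Second, a fit whose coefficients genuinely lie in the
penalty null space (a straight line, for the default second-order penalty)
must be detected by penalty energy at floating-point noise level — but a
large λ *shrinks* any fit toward the null space, so before capping, the term
is re-probed at λ = 1; only if the probe is also null is the cap (with a
warning) justified.

**Scheduling.** The fixed point is run to convergence once per distribution
parameter per outer cycle, on the first backfitting cycle, and λ is then
held fixed while backfitting and the inner iteration converge. Re-estimating
λ inside every backfitting cycle — the most literal "local" scheme — makes
the penalized objective a moving target; on some simulated datasets this
produced hundreds of step-halvings and convergence crawls, and occasionally
let the pooled and federated paths diverge at an iteration-count knife edge.
The adopted schedule converges in 5–8 outer cycles on the study conditions
and keeps the two paths numerically indistinguishable (~1e-13 on parameter
curves). A consequence worth noting: fits need fewer communication rounds
(roughly 700–900 for the four-parameter spline model below) than an
implementation that re-estimates λ every cycle would.

## P-splines and knots

`pb(x)` uses a degree-3 B-spline basis on 20 equal-width interior intervals
(basis dimension 23) with a second-order difference penalty — the
conventional defaults. Boundary knots are equally spaced extensions, not
replicated, so the basis is a proper P-spline basis; partition of unity and
an independent Cox–de Boor recursion verify the basis entrywise. The linear
trend of a smoothed covariate is written explicitly in the formula
(`~ age + pb(age)`), so `pb()` contributes only the penalized basis. Because
intercept and linear trend live both in X and in the penalty null space, the
coefficient split between them is not separately identified — the fitted
predictor is. This is the standard situation for this model class;
backfitting resolves the split deterministically from the zero start.

Knots must be identical across nodes. In a federated session they come, in
order of precedence, from (1) a user-supplied `xranges`, or (2) the
anonymized range: per-node extremes are pooled and rounded *outward* to a
multiple of a granularity (default: one significant digit of 1/32 of the
pooled range), after a k-anonymity check on every node. Outward rounding
guarantees the shared domain covers every observation, so anonymized knots
can never cause out-of-domain failures on training data (a tested
invariant). The exact rule is this package's choice; only its covering and
coarsening properties are guaranteed.

Prediction outside the knot-supported domain is an **error**, not a warning:
P-spline extrapolation is undefined, and a silently wrong reference curve is
worse than a failure.

## Federation

The pooled and federated fitters share one driver written against a node
abstraction; a pooled fit is the driver run on a single node holding all
rows. Each per-term update is fed by the elementwise sum of per-node
sufficient statistics — $C'WC$ (at most q × q with q = 23 by default),
$C'We$, the scalar weighted residual sum of squares, the count, and a
deviance contribution. Working responses and weights are computed node-side
from broadcast coefficients and never travel. Summation over nodes equals
pooled computation exactly up to floating-point ordering, which is the
entire equivalence argument; the acceptance tests assert agreement beyond
the 10th decimal for a parametric model and far beyond the 3rd decimal for
the four-parameter spline model. The one caveat is tolerance knife edges: if
a deviance change lands within floating-point noise of a stopping threshold,
one path may run one extra iteration and the agreement degrades to the
convergence tolerance — the same order of discrepancy that separate
implementations of the same algorithm exhibit.

Every payload crosses a serialization boundary that admits only plain
numeric arrays, counts its scalars into a communication log, and has
dimensions that depend on the model specification alone, never on a node's
sample size (tested by comparing logs across different n). Before any fit,
each node's metadata must pass the disclosure guard: node size ≥
`k_anonymity` (default 3), every factor category *present* on a node holds ≥
`category_min` (default 3) observations (absent categories are fine — a
country-per-node design is the canonical use case), and the total
coefficient count may not exceed `df_ratio` (default 0.33) times the node
size. Violations abort before anything is exchanged. Per-individual factor
columns are thereby rejected automatically, and subject-level random effects
are simply not part of the model language.

A pooled fit keeps the response and fitted parameters, so `residuals()`
(normalized quantile residuals) and `fitted()` work; a federated fit stores
no individual-level component and those accessors fail deliberately.

## Synthetic data

Two generators define the validation conditions; both store their generating
truth for recovery tests.

* `fg_sim_growth()`: ages uniform on [2, 18] rounded to one decimal
  (mimicking cohort age recording); height drawn from NO, BCCG or BCPE with
  a smooth monotone median curve (a polynomial plus a logistic pubertal
  acceleration, ~90 cm at age 2 to ~170 cm at 18), a slowly decaying
  coefficient of variation (~5%), constant ν = 1 and τ = 2 by default.
  Constant shape truths are deliberate: conditional height is near-normal,
  and a correct fitter should find effective degrees of freedom near the
  null-space dimension for σ, ν, τ while picking up the real curvature in μ.
* `fg_sim_sbp()`: systolic blood pressure with mean depending on sex and a
  log-normal BMI, and country-specific residual variance
  (log σ intercept 2.0, country effect 0.1), one country per node — the
  minimal heteroscedastic federation.

What these generators do **not** emulate: repeated measurements within
children, study-wave structure, measurement rounding of the response, or
covariate distributions beyond the stated ones. Passing recovery tests
therefore demonstrates correctness of the estimator under the stated
sampling models, not robustness to real cohort-data complications.

Problem sizes used by the test-suite and acceptance runs — n = 4000 over two
nodes for the blood-pressure model, n = 2000 over one/two/four/eight nodes
for the growth models — mirror the validation study design that motivated
the package.

## Known limitations

* No standard errors or confidence bands; `summary()` says so explicitly.
* Only the RS algorithm (no cross-derivative variant), only NO/BCCG/BCPE,
  only P-spline and linear terms; no random effects, which in a federated
  setting would also be a re-identification risk.
* λ is estimated by the local ML fixed point only; no global information
  criterion search.
* Residual diagnostics exist for pooled fits only.
* The communication layer is an in-process message-passing abstraction with
  a strict numeric wire format; a network transport would replace one
  function.
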