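---
title: "IPTW estimation and sensitivity analysis for rare exposures and outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IPTW estimation and sensitivity analysis for rare exposures and outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`iptwsens` estimates the causal effect of a rare binary exposure on a rare
binary outcome from individual-level cohort data, and quantifies how fragile
that estimate is. The motivating setting is perinatal: heated-tobacco-product
use in the first trimester (about 2% of a 1003-pregnancy cohort) and
placental abruption (under 1% of pregnancies). With so few exposed cases,
three things go wrong at once — propensity weights become unstable, Wald
intervals become untrustworthy, and the room for unmeasured confounding is
large. The package addresses each in turn.

## The estimation model

Let $Z_i \in \{0,1\}$ be exposure, $Y_i \in \{0,1\}$ the outcome and $X_i$ a
vector of binary baseline covariates. The propensity score
$e(x) = P(Z = 1 \mid X = x)$ is fitted by maximum-likelihood logistic
regression (`fit_logistic()`, IRLS via `stats::glm`). ATE weights are
$w_i = Z_i / e(X_i) + (1 - Z_i)/(1 - e(X_i))$.

Identification rests on the usual assumptions: no unmeasured confounding
given $X$, positivity ($0 < e(x) < 1$), and consistency. The bias analysis
below exists precisely because the first assumption is doubtful in
observational tobacco research.

Two weighted outcome models give the two effect scales:

* the **absolute risk difference** is the slope of a weighted identity-link
  Gaussian GLM of $Y$ on $Z$ — with saturated regressors this is exactly the
  difference of weighted arm means;
* the **relative risk ratio** comes from weighted modified Poisson
  regression: a log-link Poisson GLM on the binary outcome, whose
  exponentiated slope is the risk ratio. We fit it as quasi-Poisson, which
  leaves the coefficients untouched and only suppresses the integer-count
  likelihood check that prior weights would otherwise trip; the estimated
  dispersion cancels out of the sandwich product.

Both models use the HC0 sandwich variance (bread = weighted information,
meat = raw weighted score outer products, no small-sample correction) with
$z_{0.975} = 1.959964$ Wald intervals. Weights are treated as fixed, so the
frequentist intervals ignore propensity-estimation uncertainty; that
component is exactly what the Bayesian two-step quantifies. The test suite
pins both GLM routes to the closed-form saturated-model estimates and
standard errors on expanded 2×2 tables at $10^{-8}$.

## Tunable parameters

| parameter | default | units / scale | rationale |
|---|---|---|---|
| `clip_eps` | 1e-6 | probability | clips fitted propensities away from 0/1 so weights stay finite without materially moving estimates; no percentile trimming by default |
| `ci_level` | 0.95 | probability | conventional reporting level |
| separation flag | 15 | log-odds | coefficients beyond ±15 indicate (quasi-)separation; also beyond the Bayesian uniform(−10, 10) support |
| `hdi_mass` | 0.94 | probability | highest-density interval mass used in reporting |
| `chains`, `draws`, `warmup` | 4, 2500, 1000 | — | 10,000 post-warmup draws total; warmup length is a package choice (not dictated by the procedure being emulated) |
| bias grid | axes 1–15, step 0.5 | risk ratio | spans "no association" to "strong association"; 0.5 resolution is a package choice |

## The two-step Bayesian sensitivity analysis

Step 1 samples the posterior of the logistic propensity model. Priors: the
intercept gets a heavy-tailed Cauchy prior with scale 2.5 centred at
logit(0.126), the assumed population prevalence of the exposure; every
covariate coefficient gets a flat uniform(−10, 10) prior. The analogous
Cauchy anchor at logit(0.007) for the outcome prevalence is carried in
`prior_spec()` for reporting, but deliberately enters no likelihood: the
procedure is *two-step*, and the per-draw outcome stage is a weighted
frequentist fit. This is a genuine design decision — one could instead build
a jointly Bayesian treatment-and-outcome model — but the two-step form keeps
the outcome model identical to the frequentist one, so the comparison
between the two analyses isolates propensity uncertainty.

Step 2, for each posterior draw $\beta^{(m)}$: compute $e^{(m)}(X_i)$, the
ATE weights, and the weighted RD and RR. Because the outcome model contains
only an intercept and $Z$, the per-draw estimates have closed forms
(weighted arm-mean contrasts); a test verifies they equal the GLM route at
$10^{-10}$ on sampled draws. The collections over $m$ are summarised by the
posterior mean and the 94% HDI, computed as the narrowest contiguous window
containing $\lceil 0.94 n \rceil$ sorted draws. Draws with non-finite
effects are dropped and counted; more than 1% dropped is an error rather
than a silent repair.

### The sampler

No gradient-based probabilistic-programming backend is assumed; the package
implements adaptive Hamiltonian Monte Carlo directly (`hmc_chain()`):

* dual-averaging step-size adaptation targeting 0.8 acceptance;
* a windowed diagonal mass-matrix estimate (adaptation phases at 15% / 75%
  of warmup, variance shrunk toward a small floor, step size re-found after
  the mass update);
* leapfrog trajectories with nominal integration time 2.5, capped at 64
  steps, with the length drawn uniformly from the upper half of the cap —
  the jitter breaks resonances a fixed length can lock onto;
* trajectories with exploding Hamiltonian error are rejected as divergent.

The uniform(−10, 10) coefficient prior is handled by the logistic
reparameterisation $\beta_j = -10 + 20\,\sigma(u_j)$ with its log-Jacobian,
so trajectories never meet a hard boundary; draws are returned on the
natural log-odds scale. A full no-U-turn tree is not implemented; under the
package's sampler contract (any function producing independent seeded
chains), fixed-budget jittered trajectories proved sufficient — the
convergence gate below is checked, not assumed. Alternative samplers can be
plugged in via the `sampler` argument, which the test suite itself uses to
pin the posterior at the frequentist fit and verify the two-step collapses
to frequentist IPTW.

Convergence is monitored by split-$\hat R$ per propensity parameter: each
chain is halved, and $\hat R = \sqrt{((m-1)/m\,W + B/m)/W}$ compares
between- and within-half-chain variances. The default run (4 chains × 2500
draws on an n = 1000 synthetic cohort with 16 covariates) is gated at
$\hat R \le 1.01$ in the acceptance tests.

## Bounding-factor bias analysis

For an unmeasured confounder with risk-ratio associations $RR_{UE}$ (with
exposure) and $RR_{UD}$ (with outcome), both $\ge 1$, the bounding factor

$$B = \frac{RR_{UD} \times RR_{UE}}{RR_{UD} + RR_{UE} - 1}$$

caps the attenuation of an observed risk ratio: $RR_{post} = RR_{pre}/B$.
`min_joint_strength()` inverts the equal-strength case in closed form:
the smallest $x$ with $B(x, x) \ge RR$ is the positive root of
$x^2 - 2\,RR\,x + RR = 0$, i.e. $x = RR + \sqrt{RR(RR-1)}$ (the E-value).
Nullification is reported for **both** the point estimate and the
confidence bound nearer the null, because the robustness claim of interest
usually attaches to the bound: moving the lower limit to 1 refutes the
whole interval. The continuous value (e.g. 14.48 for a bound of 7.5) is
reported without rounding to any previously published integer.
Grid identities — symmetry of $B$, monotone attenuation along both axes,
$B(x,x) < x$, and the round trip
`min_joint_strength(bounding_factor(x, x)) = x` at $10^{-9}$ — are asserted
exhaustively in the tests.

## Sample-size module

`two_proportion_n()` implements the unequal-allocation normal-approximation
formula with allocation ratio $k = (1 - \pi_Z)/\pi_Z$, pooled variance
under the null and unpooled under the alternative, no continuity
correction. The unexposed risk is derived from the stated *mean* incidence
by $p_0 = \bar p - \pi_Z \cdot \Delta$ (so the prevalence-weighted mean of
the arm risks equals $\bar p$); taking the mean incidence as $p_0$ directly
is available via `baseline = "unexposed"`. `attrition_inflate()` divides by
the product of retention multipliers (default 0.70 × 0.20 × 0.70 = 0.098)
and ceilings.

Under the motivating design inputs (exposure 12.6%, mean incidence 0.7%,
detectable risk difference 0.7 points, α = 0.05, power 80%) the module
returns an analyzable total of 12,143, against the 12,836 published for
this design. No standard variant we examined (all-unpooled variance,
continuity correction, unexposed-baseline derivation) reproduces 12,836
exactly, and the published figure is also consistent in magnitude with an
analyzable ~1258 inflated through the attrition chain — the original
derivation is ambiguous. The module therefore reports its computed chain
alongside the published number and asserts no exact match; what *is*
asserted is substance: a Monte-Carlo oracle (pooled-variance score test,
2000 replicates) must reproduce the requested power within ±3 percentage
points at the returned sizes.

## The synthetic cohort generator

`generate_cohort()` emulates the structure the analysis assumes, not the
survey that produced the real data:

* 16 independent binary covariates at the marginal prevalences of the
  published cohort's characteristics table (e.g. IVF 17/1003, partner HTP
  use 163/1003). The published table's "HTP use shortly before pregnancy"
  row is excluded from the defaults: it is nearly an exposure proxy and
  would dominate the propensity model the way an instrument would.
* exposure from a logistic model; a handful of covariates carry nonzero
  log-odds effects sized from the table's implied odds ratios (own
  traditional smoking and IVF around OR 10, partner HTP around 7, partner
  traditional smoking around 3.5).
* untreated risk from a log-risk (excess-risk) model
  $p_0(x) = \exp(\gamma_0 + x'\gamma)$, with abruption risk factors
  (previous abruption, hypertensive disorders, placenta previa, tobacco
  exposure) carrying effects of OR-like size 1.5–6; the treated risk is
  $p_0(x) + \Delta$ with $\Delta = 0.07$ by default, so the risk
  difference is constant across covariate patterns and the ATE equals
  $\Delta$ exactly.
* potential outcomes are drawn by monotone coupling (one uniform per
  subject), so `mean(y1 - y0)` realises the true effect without extra
  Monte-Carlo noise, and configurations whose implied risks leave $[0,1]$
  for any covariate pattern are rejected at construction, naming the
  pattern.
* intercepts are calibrated to marginal targets (exposure prevalence
  0.023 = 23/1003; mean untreated risk 0.007): the outcome intercept in
  closed form via the Bernoulli moment generating function, the exposure
  intercept by root-finding over exact enumeration of the nonzero-effect
  patterns.
* one root seed feeds three derived stage streams (covariates, exposure,
  outcomes), so cohorts are byte-reproducible and stages independently so.
* expected case counts below 5 produce a warning, mirroring the rare-event
  instability concern, not an error.

What the generator deliberately does **not** emulate: covariate
correlations (the published table gives marginals only, so covariates are
independent unless configured otherwise), the survey sampling frame,
fraudulent-response filtering, attrition mechanisms, missing data (the
source questionnaire forced complete responses) and measurement error.
Passing recovery and coverage tests therefore demonstrate estimator
correctness under the assumed data-generating model — they do not certify
the real cohort's estimates, whose raw data are not public.

A note on realism: at the study's own scale (n ≈ 1000, ~23 exposed), the
full 16-covariate frequentist propensity fit frequently hits
quasi-separation — several covariates have no exposed carriers — and
`fit_logistic()` refuses to return a fit rather than silently delivering a
boundary MLE. That is faithful to the regime. Practical frequentist runs at
this scale should restrict to the exposure-relevant covariates; the
Bayesian module fits the full set, because its priors keep the posterior
proper.

## Numerical choices

* GLM convergence tightened to `epsilon = 1e-12` so saturated fits match
  closed forms at the $10^{-8}$ oracle tolerance.
* Propensity clipping at $[10^{-6}, 1 - 10^{-6}]$; applied before
  weighting in both frequentist and per-draw Bayesian stages.
* `round_half_up()` (ties away from zero) for flow percentages; base R's
  banker's rounding disagrees on exact ties.
* Attrition ceiling guards against float noise (`98/0.098` must give 1000,
  not 1001).
* Separation is an error naming the covariate; singular designs are an
  error naming the inestimable column.
* Effect draws identical across chains (a pinned posterior) are valid;
  split-$\hat R$ errors only on exactly constant chains.

## Problem sizes used in the test suite

Chosen to make every stochastic assertion sharp at the configured
tolerances: parameter recovery uses 200 replicates of n = 5000 confounded
cohorts (IPTW mean within 0.01 of the true 0.07 while the crude estimator
carries its built-in ≈ +0.02 confounding bias); CI calibration uses 500
replicates of n = 1500 (coverage gated to [0.90, 0.98]); ATE bookkeeping
uses a single n = 50,000 cohort; the Bayesian convergence gate runs the
full 4 × 2500-draw configuration on n = 1000.

## Known limitations

* Frequentist intervals condition on the estimated weights; only the
  Bayesian module propagates propensity uncertainty, and its outcome stage
  is itself frequentist per draw.
* The bounding-factor analysis is non-probabilistic: it bounds worst-case
  confounding, it does not model it.
* Covariate independence in the generator understates the collinearity a
  real covariate set would show, which would make separation more, not
  less, frequent.
* The sample-size module cannot arbitrate the ambiguity in the published
  12,836 derivation; it reports, it does not reconcile.
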