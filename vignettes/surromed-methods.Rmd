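---
title: "Validating a longitudinal marker as a surrogate: methods and design notes"
author: "surromed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a longitudinal marker as a surrogate: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surromed)
```

## The scientific problem

A longitudinal biomarker (think PSA in prostate cancer) is a candidate
surrogate for a time-to-event endpoint such as disease-free survival when a
sufficiently large share of the treatment effect on the event reaches it
*through* the marker. `surromed` quantifies that share with a joint model
for the marker and the event time, extended to meta-analytic data (several
trials, or centers of a multicenter trial), combined with a mediation
decomposition of the treatment effect on the survival scale.

## The joint model

For subject $j$ of trial $i$, with treatment $Z_{ij} \in \{0,1\}$ and
covariates $X_{ij}$, the observed marker at time $t$ is

$$\tilde M_{ij}(t) = M_{ij}(t) + \varepsilon_{ij}(t), \qquad
  \varepsilon_{ij}(t) \sim N(0, \sigma_\varepsilon^2),$$

where the error-free marker is

$$M_{ij}(t) = (\beta + \omega_{ij})' f(t) + \beta_M' X_{ij}^M
  + \left(\beta_{Z,M} + \nu_{M,i} + \beta_2\, g(t)\right) Z_{ij}.$$

Here $f(t)$ is a trajectory basis (by default $(1, t)'$, giving a random
intercept/slope model; a three-component basis with a sharp post-baseline
drop $f_1(t) = (1+t)^\alpha - 1$ and a long-term rise $f_2(t)$ is provided
for PSA-like markers), $\omega_{ij} \sim N(0, \Sigma_\omega)$ are
individual random effects on two of the components, $g(t)$ carries the
treatment-by-time interaction, and $(\nu_{M,i}, \nu_{T,i}) \sim
N(0, \Sigma_\nu)$ are trial-level deviations of the two treatment effects.

The hazard of the event is

$$\lambda_{ij}(t) = \lambda_0(t) \exp\!\left\{ (\beta_{Z,T} + \nu_{T,i})
  Z_{ij} + \beta_T' X_{ij}^T + \eta\, h\!\left(\bar M_{ij}(t)\right)
  \right\},$$

with $\lambda_0$ a flexible baseline hazard and $h(\cdot)$ the **link**:
the current marker level $M(t)$, its current slope $dM(t)/dt$, or the
random effects themselves (shared-random-effects link). Mediation requires
the linked quantity to depend on treatment: the shared-random-effects link
never mediates, and the slope link mediates only through a
treatment-by-time interaction — `model_spec()` warns when a requested
model makes the mediated effect structurally zero.

The long-term-rise function admits two algebraic readings,
$f_2(t) = t^{\lambda+1}(1+t)^\lambda$ and
$f_2(t) = t^{\lambda+1}/(1+t)^\lambda$; both increase from $f_2(0) = 0$
for the relevant parameter range and both are implemented
(`trajectory_basis(f2_form =)`), with the product form as the default.

## Mediation measures

Write $S_{zz'}(t)$ for the survival probability when treatment is set to
$z$ in the event process while the marker follows its trajectory under
treatment $z'$. The total treatment effect on the survival scale
decomposes as

$$\mathrm{TTE}(t) = S_{11}(t) - S_{00}(t)
 = \underbrace{S_{11}(t) - S_{10}(t)}_{\mathrm{NIE}(t)}
 + \underbrace{S_{10}(t) - S_{00}(t)}_{\mathrm{NDE}(t)},$$

and the proportion of treatment effect mediated by the marker is
$\mathrm{PTE}(t) = \mathrm{NIE}(t)/\mathrm{TTE}(t)$. Under the usual
identification conditions — well-defined treatments without interference,
consistency (the longitudinal model is taken as correctly specified for
the error-free process, so no "no measurement error" assumption is
needed), and sequential ignorability conditional on covariates *and*
random effects — the counterfactual survival is computable from the model:

$$S_{zz'}(t \mid x) = \int_\xi
  \exp\left(-\int_0^t \lambda_0(u)\, e^{(\beta_{Z,T}+\nu_T) z + \beta_T'x
  + \eta h(\bar M_{z'}(u))}\, du\right) f_\xi(\xi)\, d\xi.$$

These are assumptions about the design and the model, not testable
properties; the package documents them and computes under them.

Implementation choices:

* The individual random effects in the effect integral are integrated by
  deterministic two-dimensional Gauss–Hermite quadrature (20 nodes per
  dimension by default; doubling the resolution moves PTE by well under
  0.005). Trial-level random effects are integrated by Monte Carlo
  (`n_mc_effects`, default 5000) with one common draw set shared by
  $S_{11}, S_{10}, S_{00}$ so their differences are stable.
* The time integral uses the same fixed-order Gauss–Legendre rule as the
  likelihood, with the marker evaluated exactly at the quadrature nodes.
* Population effects average $S_{zz'}(t \mid x)$ over the empirical
  covariate distribution; for categorical covariates the weighted-category
  shortcut gives the identical result with fewer evaluations. Under fixed
  trial effects the empirical trial distribution is averaged alongside.
* PTE is never clipped — opposing direct and indirect effects can push it
  outside $[0,1]$ — but it is flagged unreliable wherever
  $|\mathrm{TTE}(t)| < 0.01$ (survival difference), since the ratio is
  uninterpretable when the arms' survival curves nearly coincide. For the
  same reason the measures should not be read at times very close to
  baseline or to the end of follow-up.
* Confidence bands come from a parametric bootstrap: parameter vectors are
  drawn from the asymptotic Gaussian law of the estimator *on the
  unconstrained scale* (covariances through their Cholesky factors), so
  every draw is a valid parameter set and no draw has to be rejected or
  repaired; bands are pointwise 2.5th/97.5th percentiles (default 1000
  draws).

The trial-level strength of association can additionally be summarized by
$R^2_{trial} = \sigma_{\nu_{M,T}}^2 / (\sigma_{\nu_M}^2 \sigma_{\nu_T}^2)$
(`r2_trial()`).

## Estimation

The baseline hazard is expanded in cubic M-splines,
$\lambda_0(t) = \sum_i c_i M_i(t)$ with $c_i = r_i^2$, so positivity is
automatic and the cumulative hazard is exact through the integrated basis
(I-splines). Squaring rather than exponentiating keeps the curvature
penalty a polynomial functional of the coefficients, computed exactly by
piecewise Gauss–Legendre quadrature of $\int \lambda_0''(u)^2 du$. Knots
default to 7 (two boundary plus five interior), interior knots at
quantiles of observed event times with an equidistant fallback.

The objective is the penalized log-likelihood
$p\ell(\phi) = \ell(\phi) - \kappa \int_0^\tau \lambda_0''(u)^2\, du$,
with $\kappa \ge 0$ user-supplied (default 5; larger values give smoother
hazards; no automatic selection is attempted). Conditional on the random
effects, the longitudinal records contribute independent Gaussian
densities around the error-free marker and the event contributes
$\lambda(T^*)^\delta \exp(-\Lambda(T^*))$, with the subject's cumulative
hazard integrated by a fixed 15-point Gauss–Legendre rule on $[0, T^*]$.

Random-effect integration follows the pseudo-adaptive rule: the
Gauss–Hermite grid (9 nodes per dimension by default) is centered and
scaled per subject at the random-effect posterior of the longitudinal
submodel fitted alone, computed once at initialization; a plain
prior-centered grid is available (`pseudo_adaptive = FALSE`). Trial-level
random effects are integrated by Monte Carlo with one fixed draw set per
trial shared across all its subjects *and across optimizer iterations*
(common random numbers), because a stochastic objective would break the
damping and line-search logic.

Maximization proceeds in stages: (1) the longitudinal mixed model alone
(closed-form marginal likelihood); (2) the survival block (hazard
coefficients, association, survival fixed effects) with the longitudinal
block held; (3) joint quasi-Newton ascent, followed by damped-Newton
(Levenberg–Marquardt) polishing steps using the finite-difference Hessian
whenever standard errors are requested — the same Hessian then serves as
the curvature estimate. Convergence requires relative objective change,
relative parameter change and gradient norm below 1e-5, 1e-5 and 1e-3.
Standard errors are the square roots of the diagonal of the inverse
Hessian of the *penalized* log-likelihood at the maximizer, delta-method
transformed to the natural scale for $\sigma_\varepsilon$ and the
covariance components. Exact event-time ties need no special handling
(parametric hazard, no risk sets); subjects must have positive follow-up
and at least one marker measurement.

Trial-level heterogeneity can be handled three ways, in increasing cost:
ignored (`trial_mode = "none"`, appropriate for many centers with small
heterogeneity — the association estimate then drifts mildly upward, a
robustness property checked in the test suite), treatment-by-trial fixed
effects (`"fixed"`, $2(K-1)$ extra parameters, suitable for a moderate
number of trials; the deviations multiply the treatment indicator, since
that is where the heterogeneity enters the generating model), or
bivariate-Gaussian random effects (`"random"`, the most expensive).

This implementation supports exactly two individual random-effect
components, the first of which must be the intercept; this covers both the
random intercept/slope model and the PSA-style model (random intercept and
long-term rise) while letting the hazard integrand factorize for speed.

## The simulator

`simulate_scenario()` generates data matching the conditions of the
package's validation studies: 800 subjects; trial membership uniform over
$K$; treatment and a binary covariate each Bernoulli(1/2); marker
$M(t) = (\beta_0+\omega_0) + (\beta_1+\omega_1)t + (\beta_{Z,M}+\nu_M)z +
\beta_2 z t + \beta_M x$ observed with $N(0, 0.3^2)$ noise; event times
from the current-level-linked hazard by inverting the cumulative hazard;
visits on a jittered 0.2-year grid truncated at follow-up (about 6.2
per subject); censoring from an independent uniform time capped at the
horizon $\tau = 3$, giving about 20% censored. Three presets differ only
in the trial structure: no heterogeneity; $K = 100$ with
$\Sigma_\nu = \begin{pmatrix} 0.086 & 0.056 \\ 0.056 & 0.086
\end{pmatrix}$; and $K = 10$ with variances 0.400 and covariance 0.280.
All randomness flows from one master seed through independent named
substreams, so each latent component (assignments, random effects, noise,
event, censoring, visits) is reproducible in isolation.

The default baseline hazard is exponential, calibrated at config load so
the pooled marginal survival (averaged over arms, the covariate and the
random effects) is 0.50 at $t = 1$ year; with the default parameters this
places the marginal event fraction at $t = 2$ at 75% and leaves roughly
11% of subjects event-free at the horizon. A constant hazard is the
simplest family consistent with the intended survival profile, and the
implied true mediation measures at $t = 1, 2, 3$ — computed by plugging
the generating parameters into the counterfactual-survival formula, never
simulated — are reproduced by the package's own mediation code as part of
the acceptance suite. A Weibull family and arbitrary anchor sets are
supported through `calibrate_baseline()`, which verifies every achieved
anchor to within 0.01 (by deterministic quadrature, cross-checked by
Monte Carlo in the tests) and refuses infeasible, increasing-survival
targets. The censoring-time range and the visit spacing were set once so
the generated censoring fraction and visit count match the stated study
conditions, and are exposed in the scenario configuration.

What the generator deliberately does **not** emulate: nonlinear (PSA-like)
mean trajectories in the shipped scenarios (the nonlinear bases are
exercised by unit tests and available to `fit_joint_model()`, not by the
presets), informative or dependent censoring, missed-visit processes,
interval censoring and competing risks. Passing recovery tests on these
scenarios therefore demonstrates correctness of the estimation machinery
under the stated generating model — not robustness to real-data
complications such as trajectory misspecification.

## Validation studies shipped with the package

The test suite validates every layer: spline identities against numeric
quadrature oracles; event-time draws against closed-form inversions; the
joint likelihood against its exact factorization when the association is
zero and against closed-form survival when the random effects degenerate;
the mediation formula against the exponential closed form; and parameter
recovery on simulated scenarios. Replicated-recovery checks use reduced
replicate counts (12 replicates for recovery and robustness, 20 for the
null-effect check, 50 in the acceptance script) with tolerances scaled as
$2\,\mathrm{SD}/\sqrt{R}$; each replicate fits the full 800-subject
dataset. Replicate fits warm-start at the previous replicate's optimum —
datasets are i.i.d., so this changes nothing but the iteration count
(verified: estimates agree to 1e-7 with cold starts).

Two finite-sample biases are expected and deliberately not "fixed": the
longitudinal slope is overestimated and the slope random-effect variance
underestimated under informative dropout at these settings, and
model-based standard errors for the longitudinal temporal parameters
underestimate the empirical spread — a known behavior of joint models of
this type. The robustness study (many centers, small ignored
heterogeneity) reproduces a mild upward drift of the association
parameter, the cost of ignoring correlated treatment-effect heterogeneity.

## Known limitations

No interval censoring, competing risks, recurrent events, cure fractions
or left truncation; one biomarker per model; no automatic $\kappa$
selection; individual-level association summaries (e.g. a Kendall's tau
accounting for the marker link) are not provided. The individual
random-effect dimension is fixed at two.
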