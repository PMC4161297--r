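---
title: "Random-effects von Bertalanffy growth models for mark-recapture data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-effects von Bertalanffy growth models for mark-recapture data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbgrowth)
```

## The problem

Annual mark-recapture studies of fish (and many other organisms) produce
sparse longitudinal size-at-age data: each tagged individual is measured at
most once per year, most individuals are seen only once or twice, and a few
are followed for many years. Estimating growth from such data faces two
coupled difficulties. First, repeated measures of the same individual are
not independent — a fish that is large for its age at first capture tends to
stay large — so pooling records as if they were cross-sectional biases
group-level growth estimates. Second, data for any single individual are far
too thin to estimate its growth curve alone.

`vbgrowth` addresses both with a nonlinear random-effects model fitted by
maximum marginal likelihood, with individual growth parameters recovered as
Empirical Bayes posterior modes. The package simulates, fits, selects among,
and validates these models.

## The model

Length-at-age follows the three-parameter von Bertalanffy growth function

$$L(t) = L_\infty \left(1 - e^{-k (t - t_0)}\right),$$

where $L_\infty$ (mm) is the asymptotic length, $k$ (1/year) the rate at
which it is approached, and $t_0$ (years) the hypothetical age at length
zero. For individual $i$ in year-of-birth cohort $j$, the two growth
parameters carry shared predictors and individual random effects on a log
link (which guarantees positivity and puts very different scales on a
common footing):

$$\log k_{ij} = \beta_0 + \beta_{1j} + \beta_2 x_j + \sigma_u u_{ij}, \qquad
  \log L_{\infty, ij} = \alpha_0 + \alpha_{1j} + \alpha_2 x_j + \sigma_v v_{ij},$$

with $u_{ij}, v_{ij} \sim N(0, 1)$ standardized individual random effects,
$x_j$ the population density experienced by cohort $j$ in its first year of
life (ind ha$^{-1}$), and cohort effects $\alpha_{1j}, \beta_{1j}$ under a
corner-point constraint (first cohort alphabetically fixed at 0, so the
intercept is identifiable). $t_0$ is a single population-level parameter: it
is poorly informed by data that start at age 1, and giving it individual
structure mostly trades off against the other two parameters. Observed
lengths are the curve plus Gaussian measurement error $\varepsilon \sim
N(0, \sigma_\varepsilon^2)$; no explicit process (growth) stochasticity is
modelled, so all within-individual correlation is carried by $(u, v)$.

At most one predictor (none, density, or cohort) enters each growth
parameter, giving the nine-model grid of `model_spec_grid()`, ranked by AIC
in `select_growth_models()`. A model with cohort predictors on both
parameters and $J$ cohorts has $2J + 4$ free parameters.

## Estimation: Laplace-approximated marginal likelihood and Empirical Bayes

The likelihood of the population parameters $\theta$ integrates the random
effects out of each individual's joint density — a product of independent
two-dimensional integrals, one per fish. Each integral is approximated by
Laplace's method: an inner damped-Newton solver (analytic gradient and
Hessian, implemented in C++; exact Newton is cheap and robust in two
dimensions) finds the joint-likelihood mode $(\hat u_i, \hat v_i)$, and the
integral is replaced by the Gaussian approximation around it,

$$-\log \int e^{-f(u,v)}\,du\,dv \approx
  f(\hat u, \hat v) - \log(2\pi) + \tfrac12 \log \det H(\hat u, \hat v).$$

The outer problem maximizes the resulting marginal log-likelihood by a
bounded quasi-Newton method (`nlminb`) with central finite-difference
gradients; inner modes are cached and warm-started across outer iterations.
Convergence is declared when the largest absolute gradient component falls
below $10^{-4}$ (the conventional strict criterion for this model class;
`vb_control(tol = )`). With $\theta$ fixed at its estimate, the per-fish
modes are the Empirical Bayes estimates of the random effects: the
standard-normal prior shrinks each fish's estimate toward the population
value, most strongly for fish seen once ("borrowing strength").

Numerical choices that matter:

* **Inner accuracy.** The inner solver runs to a gradient norm of $10^{-8}$
  and then takes up to two undamped Newton polishing steps. The Laplace
  log-determinant term is only *linearly* accurate in the inner-mode error,
  so machine-precision modes are needed for the outer finite-difference
  gradients (step $10^{-5}$, relative) to read below the $10^{-4}$
  convergence criterion. The inner line search accepts steps within a tiny
  ($10^{-11}$ relative) slack so that final Newton steps — whose true
  decrease is below floating-point rounding of the objective — are not
  rejected.
* **Bounds.** The outer optimizer works inside loose, scientifically
  motivated box bounds ($k \in [10^{-3}, 10]$ y$^{-1}$, $L_\infty \in
  [10, 5000]$ mm, $t_0 \in [-10, 5]$ y, SDs on generous log ranges).
  Unbounded quasi-Newton occasionally collapses into a degenerate optimum
  in which the curve is flat and $\sigma_\varepsilon$ absorbs all variation.
* **Ridge polish.** Cohort models have a flat, collinear direction
  (intercept vs. cohort effects) on which quasi-Newton methods stall
  slightly short of the gradient criterion; the fit finishes with up to
  three full Newton steps on a finite-difference Hessian.
* **Scales.** The three standard deviations are optimized on the log scale;
  $t_0$ is unconstrained. Default starts are scale-aware: $t_0 = -0.5$,
  $L_\infty$ intercept at $\log(1.1 \times \text{max observed length})$,
  $k$ intercept at $\log 0.3$, effect SDs at $0.1$, residual SD from a
  pooled curve fit. Multi-start jitters these with a seeded RNG; ties in
  log-likelihood (within $10^{-6}$) are broken by the smaller maximum
  gradient.
* **Degenerate limits.** With $\sigma_u = \sigma_v = 0$ the Laplace value
  reduces *exactly* to the plain Gaussian likelihood (the prior integrates
  to 1 and the curvature is the identity), so the no-random-effects model
  needs no special code path. A fish with zero observations contributes
  exactly zero — Laplace is exact for Gaussian integrands.

**Accuracy of the approximation.** Laplace is an approximation, and its
per-fish error against exact (adaptive Gauss–Hermite) integration depends
on how non-Gaussian the joint density is. At the simulation conditions used
throughout the package (residual SD 8 mm, 1–9 captures per fish, effect SDs
0.22), the test suite measures per-fish discrepancies of order $10^{-3}$ to
$10^{-2}$ — the intrinsic cost of the method, shared by any
Laplace-approximation fitter, while the implementation itself agrees with an
independently computed Laplace value to $\sim 10^{-7}$. This error is a
smooth, slowly varying function of $\theta$ and has no visible effect on
parameter recovery (see below), but it is why the package's quadrature
comparison test documents an envelope rather than agreement at machine
precision.

Uncertainty comes from the inverse finite-difference Hessian at the
optimum; intervals for positive parameters exponentiate the log-scale Wald
interval (delta-method standard errors). Profile intervals are not
implemented. Monte Carlo confidence bands for mean cohort trajectories
(`mc_confidence_bands()`) draw parameter vectors from the asymptotic normal
and take pointwise quantile envelopes of the implied mean curves.

## The synthetic-data generator

`simulate_growth()` emulates the structure of annual electrofishing
mark-recapture data: cohorts with first-year densities, correlated
individual random effects, annual sampling at ages 1–9 with imperfect
capture, size-independent survival truncation of individual histories, and
Gaussian measurement error. Defaults encode the package's reference
recovery scenario: 500 fish in one cohort, true $L_\infty = 330$ mm,
$k = 0.37$ y$^{-1}$, $t_0 = -0.38$ y, $\sigma_u = \sigma_v = 0.22$, capture
probability 0.5.

Two defaults deserve comment:

* **Residual SD 8 mm.** Field length measurements are nominally to the
  nearest mm, but the observation-model residual also absorbs everything
  the growth model leaves out (within-year timing, transient condition);
  hindcast residual scales reported for comparable stream-salmonid datasets
  are 7–12 mm. 8 mm is a realistic, fixed choice.
* **Correlation on the parameter scale.** `re_correlation` is the Pearson
  correlation between $L_\infty$ and $k$ *at the individual level* — the
  scale on which empirical correlations of Empirical Bayes estimates are
  reported. Internally it is converted to the normal-scale correlation of
  $(u, v)$ through the bivariate-lognormal map; at $r = -0.9$ the two
  differ by about 0.04, which matters at the $\pm 0.1$ recovery tolerance.
  The *fitted* model always assumes independent effects — the correlation
  is recovered empirically from the EB modes, not estimated as a prior
  parameter (freeing it invites the computational instabilities that come
  with weakly identified correlation parameters, and is deliberately not
  offered).

`trout_like_preset()` provides two ready-made study designs with 11
cohorts, cohort effects negatively correlated across cohorts on the two
parameters, positively correlated individual effects ($r = 0.6$,
$\sigma_u = 0.15$, $\sigma_v = 0.12$ — between reported real-data scales
and the reference simulation), and survival-truncated histories whose
capture-count histogram decreases monotonically from a mode at one capture.

**What the generator does not emulate** — and hence what passing tests do
not certify about real data: process stochasticity (autocorrelated
good/bad growth years within a fish), size-dependent survival or capture,
age-reading error, seasonal growth, and demographic disturbances. One
consequence is documented in the test suite: per-cohort least-squares fits
on data generated *by this model* are nearly unbiased relative to the
random-effects cohort curves (the mixture mean curve is still
vBGF-shaped to within 1%), so the strong upward $L_\infty$ bias of
least-squares fits reported on real stream-salmonid data — which the
acceptance suite probes as a directional check — does not reproduce from
model-generated data and plausibly rests on real-data features outside
this model. The corresponding test is retained and expected to fail, as a
documented negative result.

## Validation protocol

`validate_growth_model()` mirrors the standard hold-out protocol for
longitudinal growth data: fish captured more than 3 times are eligible; a
third of them (seeded; the count rounds half away from zero) keep only their first
(lowest-age) observation in the training data; the model is refitted and
the held-out later observations are predicted from each fish's EB
parameters estimated from that single retained capture. Predictions are
scored by MAE and the $R^2$ of the 1:1 predicted–observed line
($1 - SS_{res}/SS_{tot}$, negative when worse than the observed mean), and
compared with the mean length-at-age of the fish's cohort (or population,
for predictor-free models), with ages binned to integer years and missing
cells falling back to the population mean at that age, then the nearest
age. "First observation" is defined chronologically (lowest age); replicate
$r$ of a run uses seed $\texttt{seed} + r - 1$.

## Problem sizes used by the test and acceptance suites

Recovery and correlation experiments use 500-fish datasets over 3 seeds;
direction checks use the sparse preset (11 cohorts × 30 fish) over 20
seeds; confidence-interval calibration uses 200 replicates of 60-fish
datasets (observed coverage ~97% at nominal 95%); oracle comparisons use
20-fish datasets. These sizes put every experiment at the scale where the
checked quantity is informative while keeping the whole suite inside a few
minutes.

## Known limitations

* Outer gradients are finite differences, not automatic differentiation;
  the implicit-differentiation correction to the Laplace gradient is
  omitted (inner accuracy makes its contribution negligible at the outer
  tolerance, which the oracle-equivalence test corroborates).
* Wald/delta intervals only; no profile likelihood, no parametric
  bootstrap.
* Random effects are individual-level only (no random cohort effects), at
  most one shared predictor per growth parameter, and $t_0$ carries no
  structure.
* The growth family is fixed to the $t_0$-parameterized von Bertalanffy
  curve; alternative families (Gompertz, logistic) would slot into the same
  machinery but are not implemented.
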