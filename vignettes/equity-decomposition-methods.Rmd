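---
title: "Measuring and decomposing inequity in health-service utilization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and decomposing inequity in health-service utilization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concindex)
```

## The problem

Middle-aged and elderly populations differ widely in whether they receive
routine health examinations, and part of that variation tracks economic
status rather than medical need. `concindex` quantifies that association for
a binary utilization outcome in person-wave survey data, and attributes it to
observable factors. This vignette is the package's methodological account:
the model, the estimators, the numerical choices, and what the synthetic
validation does and does not establish.

## Ranks and the concentration index

Individuals are ranked by a continuous living-standard measure; we use
per-capita household consumption expenditure minus health-care expenditure,
since self-reported consumption is less misreported than income and health
spending is not part of discretionary living standard. A negative net value
is retained — the index needs only the ordering, and a household that spent
more on health care than its total consumption still has a well-defined
(bottom) rank.

The fractional rank of record *i* is the weighted midpoint rank

$$r_i = \frac{\sum_{j: x_j < x_i} w_j + w_i/2}{\sum_j w_j},$$

with records tied on the living standard all receiving the midpoint of their
tied block. With equal weights and no ties this is $(i - \tfrac12)/n$ — a
constant shift of the conventional $i/N$ rank. Since the index below only
uses the covariance with the rank, and covariance is invariant to constant
shifts, the midpoint convention changes nothing in the estimate while giving
a deterministic, weight-coherent treatment of ties.

The concentration index of outcome $y$ with weighted mean $\mu > 0$ is

$$C = \frac{2}{\mu}\,\mathrm{cov}_w(y, r),$$

with the **population** covariance (total-weight divisor). That divisor is a
deliberate choice: with the $n-1$ divisor the two-record example
$y = (0, 1)$ would give $C = 1$, violating the $|C| \le 1 - \mu$ bound that
binary outcomes must satisfy; the population divisor gives $C = 0.5 = 1-\mu$
exactly at the boundary. $C$ equals twice the area between the concentration
curve and the equality diagonal; `ci_from_curve()` computes that area by the
trapezoid rule over the per-record grid and agrees with the covariance
formula within $2/n$ on any dataset (exactly, for equal weights) — the
package tests exploit this as a dual-route check.

**Standard errors.** The published tables this methodology descends from
report 95% intervals without stating a variance formula. We use the
"convenient regression": regressing $2\sigma_r^2\, y_i/\mu$ on $r_i$ by
weighted least squares returns $C$ as the slope, and its
heteroskedasticity-robust (HC1) standard error is a delta-method standard
error for the index. Intervals are $C \pm 1.96\,\mathrm{se}$. This estimator
treats the ranks as fixed, which is the standard simplification; no claim is
made that it reproduces any particular published interval.

Stratified analyses (`ci_by_group()`) recompute ranks **within** each
stratum-wave cell: a rural resident's rank is their position in the rural
distribution of that wave. Cells below 30 records are flagged rather than
suppressed.

## Decomposition and horizontal inequity

Because the outcome is binary, the utilization model is a probit,

$$\Pr(y = 1 \mid x, z) = \Phi\!\big(\alpha + \textstyle\sum_j \beta_j x_j +
\sum_k \gamma_k z_k\big),$$

with need variables $x_j$ (age group, sex, disability, chronic disease) and
controls $z_k$ (residence, region, education, marital status, insurance,
economic status, smoking, drinking), each dummy-coded against a fixed
reference (west, female, youngest band, low education, married, uninsured,
low tertile, non-smoker, non-drinker, no disability, no chronic disease).
The decomposition linearizes this model with **average marginal effects**
$\beta^m_j = \overline{\phi(x_i'b)}\, b_j$ — the sample-averaged derivative
of the predicted probability. Average (rather than at-the-means) effects are
the standard linearization choice and keep every record's curvature in play.
Then

$$C = \sum_j \frac{\beta^m_j \bar x_j}{\mu} C_{x_j}
    + \sum_k \frac{\gamma^m_k \bar z_k}{\mu} C_{z_k}
    + \frac{GC_\varepsilon}{\mu},$$

where $C_{x_j}$ is the concentration index of the regressor itself over the
same ranks and each summand is that factor's *contribution*. Numerically we
compute each contribution as $2\beta^m_j \mathrm{cov}_w(x_j, r)/\mu$ — the
algebraically identical product form — which stays defined even when a
regressor mean is zero, and we obtain the residual as the **exact remainder**
$C - \sum \text{contributions}$, so the additivity identity holds to machine
precision on every run. The direct route, the generalized concentration
index of $y - \sum_j \beta^m_j x_j - \sum_k \gamma^m_k z_k$, is also reported
(`residual_gci`); because covariance is linear the two coincide analytically,
and the tests assert their numerical agreement.

The **horizontal inequity index** removes the legitimate part:
$HI = C - \sum_j (\text{need contributions})$. A positive $HI$ says that
among the equally needy, the richer use more services. `hi_gap()` is the
urban-minus-rural difference of stratum HIs, the headline trend statistic for
urban–rural comparisons.

Percent contributions divide by $C$; when $|C| < 10^{-6}$ they are
suppressed with a warning rather than printed as meaningless huge
percentages.

**Economic status in the regressor set.** By default economic status enters
as within-wave tertile dummies of the net expenditure (medium, high vs.
low), built by `assign_tertiles()` with type-1 quantile cuts — ties at a cut
all fall to the lower group, deterministically, and each wave is cut
separately because economic position is wave-specific. The pipeline
alternatively accepts the log of the living standard as a continuous control
(`economic = "log"`); the two conventions answer slightly different
questions and the package takes no position on which a given published table
used.

Each wave is analysed as an independent cross-section; modelling
within-person dependence over waves is out of scope.

## The association model

`fit_fe_logit()` reports the conventional factor analysis: a pooled
cross-section logit per residence stratum with survey-year dummies plus the
full covariate set, exponentiated to odds ratios with Wald 95% intervals.
"Two-way fixed effects" is implemented as year dummies plus region dummies —
individual fixed effects are deliberately *not* used, since time-invariant
covariates (sex, education) would be unidentifiable under them. Reference
categories print OR = 1.00.

## The synthetic generator and its oracle

`generate_panel()` draws a panel designed to emulate a CHARLS-like
ageing-cohort survey, with every generating parameter known:

* **Defaults are the study conditions.** 11,496 individuals over waves
  2011/2013/2015/2018; covariate marginals matching the descriptive
  composition of such a cohort (52.85% male, 67.90% low education, 94.55%
  insured, 4.08% disabled, 67.09% chronic disease, 82.3% rural); log-normal
  net expenditure with mean 5419.10 and SD 5472.43 currency units; per-wave
  intercepts calibrated so expected utilization equals 29.45/20.69/25.40/
  32.05%. True probit coefficients are modest effects in the direction and
  rough size seen in utilization models for this population (e.g. 0.45 for
  ages 61–70, 0.10 for higher education, 0.15 for insurance), set once as
  scientific defaults. The default `rank_gradient` — the coefficient on the
  fractional income rank in the linear index — is 0.05, producing a true
  index of the small positive magnitude such surveys show.
* **Panel structure.** Individuals persist across waves. Age in years is
  drawn uniformly within the baseline bracket and advances with calendar
  time, re-bracketed each wave; all other covariates are fixed;
  log-expenditure is an AR-style mix of a persistent individual component
  (share `persistence`, default 0.7) and a wave-specific shock.
* **Correlation channel.** By default covariates are independent of income.
  A Gaussian-copula `rank_correlation` per covariate ties its latent to the
  persistent income component, with higher listed levels becoming more
  likely for richer individuals — this is how tests induce, say, an
  education–income gradient. Real surveys have richer correlation structure
  than single-channel copulas; the generator imitates marginals and one
  controlled dependence channel, nothing more.
* **Step law.** `step_threshold = t` replaces the probit draw with the
  deterministic $y = \mathbf 1(r > t)$, whose index has the closed form
  $1 - \mu$; with $t = 0.5$ the truth is exactly 0.5.

`true_ci_oracle()` computes the population index implied by a configuration
by numeric integration: $C = (2/\mu)\int_0^1 (r - \tfrac12)\,E[Y\mid r]\,dr$
on a midpoint grid of 10,001 rank nodes, with $E[Y\mid r]$ obtained by exact
enumeration of the discrete covariate law (sequential convolution of the
coefficient atoms; copula-correlated covariates are conditioned on the rank
through their latent normals). Intercept calibration inverts the same
integral with `uniroot` on an 801-node grid — accurate to far below
Monte-Carlo resolution. For multi-wave configurations the oracle evaluates
the baseline age distribution, so it is exact for the first wave; later
waves drift slightly as the cohort ages into higher-utilization brackets
(visible as a 2–3 point rise in later-wave rates), which is why all
oracle-based tests use single-wave configurations.

**What passing tests show — and don't.** Agreement between the estimators
and the oracle on synthetic data validates the *estimating machinery*:
ranks, index, curve, decomposition accounting, marginal-effect computation,
inequity logic. It does not certify behaviour under features the generator
lacks — informative sampling weights, item nonresponse patterns, multi-way
covariate dependence, misspecified outcome links — so conclusions about any
real survey still rest on that survey's own design.

## Numerical choices and degenerate inputs

* Weighted moments use the population (total-weight) divisor throughout, so
  duplicating a record is *exactly* equivalent to doubling its weight.
* A constant outcome returns index 0 exactly (zero covariance), with an
  undefined standard error rather than a spurious one.
* Zero outcome mean, all-zero weights, curves with zero total outcome, and
  tertiles on fewer than three records are errors, not NaNs.
* Rank-deficient probit designs are an error naming the collinear columns;
  covariates constant within a stratum (residence, inside a residence
  stratum) are dropped with a message.
* Non-integer sampling weights switch the GLM family to quasi-likelihood,
  which leaves coefficients and marginal effects unchanged.
* Hypothesis tests in descriptive tables use 0.05 conventions with no
  multiplicity correction; indices print to 4 decimals and percentages to 2,
  with full precision retained in returned objects and JSON.

## Problem sizes used in validation

The shipped test suite exercises parameter recovery at n = 20,000
(probit coefficient ±0.05; odds ratio ±0.15), oracle agreement at
n = 5,000 and 50,000 (within 4 standard errors), the null and step-law
checks at n = 50,000, bound and curve-equivalence sweeps over 1,000 and 100
random datasets, and the inequity-attribution checks (need-driven gradient
→ HI ≈ 0; control-driven gradient → HI ≈ C) at n = 50,000 with a tolerance
of 0.02 on indices near 0.07 — chosen to separate the linearization error of
the average-marginal-effect approximation (a percent-level effect at these
coefficient sizes) from genuine attribution failures.

## Known limitations

* The decomposition inherits the linear approximation of a nonlinear model;
  its residual mixes genuine unexplained inequality with linearization
  error, and contributions carry no standard errors.
* The horizontal inequity index depends on the need/control partition, which
  is an analytical commitment, not an estimate.
* No survey-design variance, no dominance tests for curves, no normalized
  (Wagstaff/Erreygers) index variants for bounded outcomes, and no
  within-person longitudinal modelling.
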