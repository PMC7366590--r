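---
title: "Forecasting the budget impact of new medicines: model, validation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting the budget impact of new medicines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bipanel` forecasts the monthly budget impact (BI, list price × volume) of
drug products from a national sales panel and quantifies how accurate such
forecasts are as a function of how much of the product's own history is
available. This vignette is the package's account of the science: the
model and its assumptions, the validation design, what the synthetic
cohorts do and do not emulate, and the numerical decisions a maintainer
would want written down.

## The model and its assumptions

For product $i$ in month $t$ (months since the product's first BI record,
$t = 1, 2, \dots$):

$$\log \mathrm{BI}_{it} = x_{it}'\beta + b_{0i} + b_{1i}\,t +
\varepsilon_{it}, \qquad
(b_{0i}, b_{1i}) \sim N_2(0, G), \qquad
\mathrm{corr}(\varepsilon_{it}, \varepsilon_{i,t+h}) = \phi^{|h|},\;
\mathrm{var}(\varepsilon_{it}) = \sigma^2 .$$

The assumptions this encodes, in order of how consequential they are:

* **Log scale.** Monthly expenditure is strongly right-skewed across
  products; the log transform makes a linear model with additive Gaussian
  components tenable and makes multiplicative errors the natural currency.
* **Product-level exchangeability.** A product is characterised by
  regulatory covariates fixed at marketing authorization — tumor site,
  molecule type, orphan designation, the combined conditional/exceptional
  approval flag (CE), FDA first-in-class (FiC) — plus its own random
  intercept and uptake slope. Nothing product-specific beyond these enters;
  indication extensions, price cuts and patent expiry are deliberately out
  of model.
* **Smooth time dependence.** Uptake curves are built from $t, t^2 \dots
  t^6$ and $\sqrt t$ interacting with the covariates, at most one time
  transform per covariate. This family is flexible enough for
  saturating and accelerating launches but cannot express change points.
* **AR(1) residuals.** Within a product, month-to-month wiggles are
  positively correlated with geometrically decaying memory. The AR
  parameter is shared across products, as are $G$ and $\sigma^2$.

The random-effects and correlation structure are *fixed* properties of the
model family; only the fixed-effects structure is searched over.

## Parameters that matter

| parameter | meaning | units | default | why |
|---|---|---|---|---|
| `t_max` | horizon of records and predictions per product | months | 45 (robustness run 42) | the forecasting window the method is validated for |
| `min_cap_eur` | floor on predicted monthly BI | EUR | 5000 | below this, errors are macro-economically irrelevant but huge on the log scale |
| `max_cap_factor` | ceiling = factor × max monthly BI in the dataset | — | 2 | stops pathological extrapolations (e.g. beyond a country's drug budget) |
| `split_month` | cohort boundary; launches on/after it are validated | year-month | `"2012-05"` | balances training-pool size against validation follow-up |
| `p_enter` | Wald gate in the stepwise search | — | 0.10 | permissive enough for prediction-oriented selection |

Caps apply to predictions only — observed records below €5000 exist and are
never altered. In the dual-horizon run the two capped predictions are
averaged per `(product, t_data, t_pred)` cell; averaging happens after each
run's own capping, since each run's scenario analysis depends on its own
caps.

## Validation design

The rolling forecasting origin simulates the passage of time. For each
validation product $k$ and each `t_data` from 0 upward, the cycle's split
date is $k$'s first record month plus `t_data`; training contains every
other product's records strictly before that date (each product trimmed to
its first `t_max` months) plus the first `t_data` records of $k$. The model
structure is selected once per horizon on the initial training set and then
held fixed; coefficients are re-estimated every cycle. Months
`t_data + 1 … t_max` are predicted, capped and scored with the symmetric
error $e^{|\ln(\mathrm{obs}/\mathrm{pred})|}$. A fully observed product
contributes $t_\mathrm{max}(t_\mathrm{max}+1)/2$ cells (1035 at 45
months). The construction makes leakage impossible by definition, and the
test suite audits every cycle for it anyway.

Interpretive decisions the design required:

* A product whose *first* record falls exactly on the split month is
  validation, not training (the boundary phrase "first record after this
  date" is read inclusively on the validation side).
* Whole products are assigned to one side by first-record date; a product
  does not straddle the boundary.
* "Mean of the absolute individual predictions" across the two horizons is
  read as the plain arithmetic mean of the (positive) euro-scale
  predictions; "absolute" is emphasis, not a modulus.
* Categorical reference levels and level registries are fixed once from
  the full covariate table, so every refit across cycles dummy-codes
  identically.

## Estimation and numerical choices

* **Likelihood.** $-\ell = \tfrac12 \sum_i [n_i \ln 2\pi + \ln|V_i| +
  r_i'V_i^{-1}r_i]$ with $V_i = Z_i G Z_i' + \sigma^2 R_i(\phi)$. Because
  every series lives on the grid $1..n_i$, $V_i$ depends only on the
  parameters and $n_i$; products are grouped by series length and each $V$
  is Cholesky-factored once per evaluation. This is exact, not an
  approximation, and is what makes thousands of refits affordable.
* **Profiling and conditioning.** $\beta$ is profiled out by GLS solved
  via QR on the whitened design rather than normal equations; the $t^6$
  column reaches $8.3\times10^9$ at $t=45$ and the normal equations would
  square that condition number.
* **Parameterization.** Optimization runs unconstrained: log-Cholesky of
  $G$, $\log\sigma^2$, $\mathrm{atanh}\,\phi$. BFGS, relative tolerance
  `1e-8` on $-\ell$, at most 500 iterations.
* **Starting values and the ridge.** The likelihood has a well-known weak
  ridge where the random-intercept variance trades off against a high-φ
  AR(1) process; a single flat start (G = 0.1 I, φ = 0) can land on it.
  The optimizer therefore runs from a fixed, deterministic pair of starts
  — a method-of-moments start (per-product OLS intercept/slope covariance,
  pooled residual lag-1 autocorrelation) and the flat start — and keeps
  the better optimum. Refits of the same data are bit-identical. On
  simulated cohorts of 200 products × 45 months every optimum checked
  coincided with `nlme::lme`'s to six decimals.
* **ML, not REML.** The stepwise search compares AICs across different
  fixed-effects structures, which is invalid under REML. All AICs are
  ML-AICs with $k = p + 5$ (fixed coefficients plus three $G$ parameters,
  $\sigma^2$ and $\phi$) — stated explicitly because AIC conventions
  differ.
* **Stepwise order of criteria.** Candidates are ranked by AIC; the
  best-AIC candidate is accepted only if its Wald p < 0.10, otherwise the
  next-best improving candidate is considered. AIC ties within `1e-6`
  break by enumeration order. Multi-level categoricals use the joint Wald
  chi-square; a likelihood-ratio gate is available as a switch
  (`test = "lr"`). The time main effect is an ordinary candidate, not
  forced in.
* **Prediction.** Conditional on the product's BLUPs when it contributed
  data to the fit, population-level otherwise; marginal over the AR(1)
  process (residual autocorrelation sharpens estimation but is not used to
  forecast future residuals). Back-transform to euros is plain
  $\exp(\hat y)$ with no smearing correction — a documented source of mild
  downward bias, accepted because predictions are compared to observed
  euros directly.
* **Degenerate inputs.** Unseen categorical levels at prediction time map
  to the reference level with a warning (a validation run must not die
  mid-stream); fits require ≥ 2 products and more observations than
  parameters; non-converged fits are flagged, never returned silently;
  failed refit cycles are excluded from metrics with a logged count and a
  run-level warning above 5%.

## What the synthetic cohorts emulate — and what they don't

The original national sales panel is proprietary, so all tests and
demonstrations run on synthetic cohorts drawn from the model's own
generative process: covariates by prevalence, $(b_{0i}, b_{1i})$ bivariate
normal, stationary AR(1) residuals with marginal variance $\sigma^2$
(innovation variance $\sigma^2(1-\phi^2)$), euros as the exponential
rounded to cents. `paperlike_config()` pins the study's cohort *shape*:
launch dates stratified so the 2012-05 split yields exactly 25 training and
44 validation products, series of up to 45 months censored at the panel
end (late launches are shorter — training products average ~33 months,
validation ~27). The source study reports no distributional parameters of
the real data, so absolute euro levels (intercept ≈ €30k/month), variance
components ($G$ = diag(1.0, 0.004) with slight negative correlation,
$\sigma^2$ = 0.25, $\phi$ = 0.6) and covariate prevalences are this
package's own choices of realistic magnitudes, fixed once and documented
here.

Consequently, passing tests show that the *method* behaves as claimed
under its own assumptions — parameters are recovered, planted structure is
found, errors shrink with accumulating data and plateau, caps and leakage
guarantees hold. They cannot show that real drug markets satisfy those
assumptions: real uptake has change points (new indications, price
renegotiations, competitor entry), covariate effects need not be
log-linear in time, and real residuals need not be AR(1). Numerical
results quoted anywhere in the package (e.g. the README example) are
computed on synthetic cohorts and are not estimates of real-world
accuracy.

## Problem sizes used by the checks

The test suite exercises: likelihood equality with a dense
multivariate-normal oracle on ≤ 12-observation instances (tolerance
`1e-8` relative); parameter recovery within 3 Monte-Carlo standard errors
over 20 replicate cohorts of 200 products × 45 months; stepwise recovery
of a planted $\sqrt t$ interaction in ≥ 18/20 replicates at 200 products;
a full leakage audit and the cell-count identity on a 45-month horizon;
and the qualitative error-vs-data decline on a reduced study-shaped cohort
of 30 products with a 15-month horizon and a single-horizon run — sizes
chosen so each property is tested at meaningful scale while the whole
suite stays fast enough to run routinely.

## Known limitations

* Accuracy statements transfer to real panels only to the extent the
  model's assumptions hold there (see above).
* $\exp$ back-transformation without smearing biases euro-scale
  predictions downward by roughly $e^{\sigma^2/2}$ relative factors when
  residual variance is large.
* The stepwise search is greedy; it recovers supersets of strong true
  structure but is not an oracle for the generating model.
* The €5000 floor and ×2 ceiling are policy choices, not estimates; the
  scenario machinery (`scenario_caps()`) exists precisely to show their
  influence.
* Single shared $G$, $\sigma^2$, $\phi$ across products; no heteroscedastic
  or ARMA extensions.
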