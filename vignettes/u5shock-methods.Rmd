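---
title: "Methods: elasticity estimation, scenario projection, and uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: elasticity estimation, scenario projection, and uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(u5shock)
```

## The model

`u5shock` quantifies how economic contractions translate into under-5
deaths in low- and middle-income countries. The statistical core is a
country-specific Preston-curve elasticity: on a panel of countries
$j$ and years $t$,

$$\log \mathrm{U5MR}_{j,t} = \alpha_j + \beta_{1,j}\,\log \mathrm{GDP}_{j,t}
  + \beta_2' Z_{j,t} + \beta_3' H_{j,t} + \varepsilon_{j,t},
  \qquad \varepsilon_{j,t} \sim N(0, \sigma^2)$$

where $Z$ are socio-economic covariates (electric power consumption,
women's parliamentary representation, total fertility) and $H$
health-service covariates (physician density, DPT coverage); region and
income-group dummies enter the fixed effects. Model 1 drops $Z$, $H$ and
the group dummies. Both logs are natural logs: $\beta_{1,j}$ is then the
elasticity of the mortality rate with respect to GDP per capita, and
elasticities are invariant to the log base anyway.

$\alpha_j$ and $\beta_{1,j}$ decompose into a global fixed part plus
mean-zero country deviations, modelled as a correlated bivariate normal
random effect. Variance components are estimated by REML (`lme4`), fixed
effects by GLS at the REML optimum, and the reported country slope is the
fixed mean slope plus the country's BLUP deviation. When the estimated
intercept–slope correlation collapses to the boundary ($|\rho| \to 1$ or
undefined), the model is refitted with independent components — the
correlated structure is preferred because it is the one closed under a
translation of $\log$ GDP (rescaling GDP must not change slopes).

**Slope standard errors.** The Monte Carlo needs a per-country sampling
scale for $\beta_{1,j}$. We use
$se^2(\beta_{1,j}) = \widehat{\mathrm{Var}}(\hat\beta_1^{fix}) +
\mathrm{Var}(b_{1,j} - \hat b_{1,j} \mid y)$ — fixed-slope sampling
variance plus the conditional (posterior) variance of the BLUP deviation.
The cross-covariance between the two is not exposed by lme4 and is
omitted; the acceptance suite checks the consequence directly: across 100
seeded replicates (30 countries, 31 years, $\sigma = 0.05$) empirical
coverage of the nominal 95% intervals is ~91%, meeting the ≥ 90%
criterion. The omission of the cross term makes the intervals slightly
anti-conservative; users needing calibrated per-country intervals should
treat them as approximate.

**Degenerate noise.** With $\sigma^2 = 0$ the likelihood is singular and
REML optimisers misbehave. `fit_elasticity()` detects this case (the
saturated per-country-line regression has essentially zero residual
variance) and returns the exact least-squares solution per country with
$se = 0$. This is not a shortcut: with no residual noise the mixed model's
generating parameters *are* the per-country lines, and the package
recovers them to 1e-6 as required.

**Shrinkage.** BLUP slopes are shrunken towards the pooled slope. The
folk rule "each BLUP lies between the country's own OLS slope and the
pooled slope" is exactly true only for slope-only random effects; with a
joint intercept–slope BLUP the slope borrows strength from the intercept
deviation and can land slightly outside that bracket. The test suite
therefore asserts the aggregate property (BLUPs strictly closer to the
pooled slope than OLS, deviations in the same direction) rather than
pointwise betweenness.

Countries contributing fewer than 5 usable rows are excluded from fitting
(slope identification), with a warning.

## Scenario projection

A scenario removes a fraction $r \in \{0, 0.05, 0.10, 0.15\}$ of the 2019
(base-year) GDP per capita. The projected rate is the model prediction at
the reduced GDP with the naive exponential retransformation:

$$\mathrm{U5MR}_j(r) = \exp\!\big(\alpha_j + \text{covariates} +
  \beta_{1,j} \log((1-r)\,\mathrm{GDP}_j)\big)
  = \mathrm{U5MR}_j(0)\,(1-r)^{\beta_{1,j}}.$$

No smearing correction is applied: the published per-country tables are
internally consistent exactly under the naive retransformation (scenario
ratios are exactly $(1-r)^\beta$), and a smearing factor would cancel out
of additional deaths anyway because it multiplies baseline and scenario
alike. Deaths apply the rate to the under-5 *population* of the
population year (2020): $\text{deaths} = \mathrm{U5MR} \times
\text{pop}/1000$. Weighting by population rather than live births departs
from the demographic convention deliberately — it is the literal rule of
the methodology being operationalised, and the only weighting consistent
with its published ~19.2M baseline total. Baseline deaths are the model
prediction at 2019 GDP (the $r=0$ scenario), not the observed 2019 U5MR,
so that all four scenarios live on the same scale and
$\text{additional} = \text{deaths}(r) - \text{deaths}(0)$ is exactly the
elasticity identity.

**Effective intercepts.** For projection, each country's covariate terms
are frozen at its most recent usable row: the stored `alpha` is the fitted
log-prediction at that row minus $\beta_{1,j} \log \mathrm{GDP}$, so a
serialised fit (JSON) projects identically to the in-memory one.

**Interval bounds.** Per-country 95% bounds are
$\exp(\log\text{pred} \pm 1.96\, s_{pred})$ with
$s_{pred}^2 = x'\,\widehat{\mathrm{Var}}(\hat\beta^{fix})\,x +
q'\,C_j\,q + \sigma^2$ (fixed-effect row variance, conditional BLUP
covariance with $q = (1, \log g)$, plus residual variance — a prediction
interval on the log scale). By construction they are log-symmetric,
`upper/point = point/lower`, which is the shape the published bounds
exhibit; how the original bounds were computed is unstated, so only this
shape is treated as normative. Additional-deaths bounds are differences
of the corresponding scenario and baseline bounds — an interpretation,
flagged as such.

## Monte Carlo uncertainty

Each of `n_iter` (default 500) iterations draws every country's slope
independently, $\beta^*_{1,j} \sim N(\beta_{1,j}, se^2_j)$, and
re-evaluates $\text{deaths}_j(r) = D_{0j}\,(1-r)^{\beta^*_{1,j}}$ with the
baseline deaths $D_{0j}$ held at their point estimates — only the impact
parameter is sampled; intercepts, covariate coefficients and variance
components stay fixed. Anchoring the baseline makes the sampled quantity
the additional-deaths total and yields the closed-form check
$E[D_0 c^{\beta}] = D_0 \exp(\mu \ln c + \tfrac12 \sigma^2 \ln^2 c)$ used
in the acceptance suite (matched within 3 MC standard errors at 200,000
iterations). Summaries are the sample mean, SD ($n-1$), and an empirical
percentile interval (type-7 quantiles) — percentile rather than
normal-approximation, being distribution-robust and exactly reproducible.

Draws use one substream per country, seeded deterministically from the
root seed and the country code, so results are bit-identical under
country reordering and fully reproducible per seed. By Jensen's
inequality ($c^\beta$ convex in $\beta$ for $0 < c < 1$) the MC mean of
additional deaths slightly exceeds the point estimate when $se > 0$; the
published side-by-side totals show the same signature.

## Imputation

GDP per capita: each missing value is the mean of the five most recent
preceding non-missing values (previously imputed values count), filled
left-to-right; leading gaps are back-filled from the earliest five
available values. A trailing rather than centred window because the
binding case is extending series to the 2019–2020 endpoints, where a
centred window does not exist.

Covariates: "multivariate normal regression" is implemented as a chained
linear-Gaussian scheme — initialise missing cells at variable means, then
repeatedly regress each incomplete variable on the other covariates plus
log GDP and year (OLS on its observed rows) and replace its missing cells
with conditional predictions, until the largest standardised change drops
below `tol` (default 1e-6, `max_iter` 50). The default is deterministic
conditional means (reproducible tests); a `stochastic` switch adds
residual draws. Percentage variables are clamped to [0, 100] on imputed
cells only; observed cells are never altered. Each variable must be ≥ 30%
observed. Singular designs drop the offending predictor with a logged
warning; non-convergence is a reported warning, not an error. This is an
interpretation — the original appendix describing the scheme is not
available — and is labelled as such.

## The synthetic world

`generator_config()` states the emulated world once: 129 countries,
1990–2020, elasticities $\beta_j \sim N(-0.2845, 0.05^2)$ (mean calibrated
to the ~1.470% per-5%-reduction increments the published country rows
imply — a calibration choice, not a published parameter), intercepts
$N(6.6, 0.35^2)$, residual SD 0.1, lognormal GDP growth (2% mean, 4% SD)
from income-band-consistent initial levels, under-5 populations
log-uniform on $[10^5, 2\times10^7]$, covariate processes with
deliberately *mild* log-GDP dependence (elasticities 0.1–0.4, so Model 2
is distinguishable from Model 1 without the covariates being GDP aliases),
levels calibrated to published 2010/2015/2019 descriptive means, and
per-variable year-band missingness matching the published shares (e.g.
physicians 17.05% missing around 2010, 100% after 2018). Missingness is
MCAR by default with a MAR switch that tilts masking towards poorer
country-years while preserving the mean rate.

What a green test establishes: the pipeline recovers parameters it
generated under the model's own assumptions, at realistic sizes and
missingness. What it does not: real WDI covariance structure, serially
correlated shocks, measurement error in U5MR, or any claim that the real
2020 elasticities equal the generator's. The published headline totals
are not reproducible without the September-2020 WDI/WPP snapshots, and no
test pretends otherwise — the acceptance targets are internal-consistency
projections of published single-country rows.

## Numerical choices and edge cases

- Missing markers are `NA`/empty cells, never 0 (zero is a legal covariate
  value). Duplicate (country, year) keys are errors, not last-wins.
- The LMIC filter is strict `gni < 12375` current US$; the income-group
  label is authoritative only when GNI is absent.
- Rendered death counts round half-up at output time only; all sums,
  shares and ratios are computed on unrounded values. One consequence,
  verified against the published table: independently rounding deaths and
  additional-deaths columns can make the printed subtraction identity off
  by one death.
- Top-N tables sort by additional deaths descending with country-id
  tie-break, so output is deterministic.
- `run_scenarios()` requires a base-year GDP and population-year under-5
  population per country; countries lacking either after imputation are
  excluded from totals with a warning and an exclusion list, never
  silently zero-filled.

## Known limitations

Association, not causation; a one-year horizon with no dynamics; slopes
sampled marginally in the MC (no joint posterior of variance components);
no autocorrelation or country-specific time trends; no live-births
denominators. The additional-deaths interval construction is one of
several defensible readings of the published bounds.
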