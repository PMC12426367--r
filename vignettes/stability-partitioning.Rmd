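---
title: "Partitioning harvest-portfolio stability and asynchrony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning harvest-portfolio stability and asynchrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finstab)
options(finstab.verbose = FALSE)
```

## The model

`finstab` treats a region-year as a species × month panel of one measured
quantity — biomass, harvest mass, dockside value or trips — and asks how
the stability of the *aggregate* monthly series relates to the stability
of its parts.  With per-species sample SDs $\sigma_i$ and means $\mu_i$,
and the column-sum series having mean $\mu_R$ and SD $\sigma_R$:

$$S_{\mathrm{agg}} = \frac{\mu_R}{\sigma_R},\qquad
\bar S = \frac{\mu_R}{\sum_i \sigma_i},\qquad
\phi = \frac{\sum_i \sigma_i}{\sigma_R},\qquad
\mathrm{SAE} = \frac{\sum_i \sigma_i}{\sqrt{\sum_i \sigma_i^2}},\qquad
\mathrm{CPE} = \frac{\sqrt{\sum_i \sigma_i^2}}{\sigma_R}.$$

The identities $S_{\mathrm{agg}} = \phi\,\bar S$ and
$\phi = \mathrm{SAE}\times\mathrm{CPE}$ are exact, and
`partition_stability()` asserts them to a relative $10^{-10}$ on every
call.  Asynchrony $\phi \ge 1$, with equality when all species are
scalar multiples of one series; $\mathrm{SAE}\in[1,\sqrt n]$ grows with
richness and variance evenness; $\mathrm{CPE}>1$ indicates negative
covariances (compensation), and is the inverse of the square-rooted
variance ratio.

Two conventions matter numerically and are fixed:

* **Sample SDs ($T-1$ denominator) throughout.**  With only $T = 5$
  survey months per year the choice is consequential for the $S$'s;
  the dimensionless ratios $\phi$, SAE, CPE are nearly invariant to it
  because numerator and denominator change together.
* **Degeneracies are typed errors, not numbers.**  A constant aggregate
  series (perfect compensation), an all-constant panel, or a zero mean
  raises a classed condition with a machine-readable code
  (`perfect_compensation`, `all_constant`, `zero_mean`);
  `partition_by_year()` catches these and records the region-year as a
  flagged missing cell.  Species with $\sigma_i=0$ but $\mu_i>0$ are
  retained: they contribute to $\mu_R$ but not to $\sum\sigma_i$.

## Annual indicators

Per region-year the package computes: the **seasonal harvest ratio**
(mean monthly total harvest in the closure∩survey months over the mean in
the open survey months — with survey months {3,5,7,9,11} and a March–May
closure the numerator months are {3,5} and the denominator {7,9,11};
April, closed but unsurveyed, is excluded); **harvest timing** (the
harvest-weighted mean month, over all twelve months by default with a
survey-months variant); an **effort index** (mean across portfolio
species of each species' trip total over the survey months — the
alternative reading, a mean of monthly trip counts, is available behind
`method = "monthly_mean"` without being endorsed); **portfolio yield and
value** (annual sums); and inverse-CV **stabilities** of total harvest
over the survey months ($S_{\mathrm{S}}$) and all twelve months
($S_{\mathrm{L}}$), plus 12-month **value stability**.  Values can first
be deflated to a base period with a monthly price index
(`deflate_values()`); deflation is applied monthly before summation,
a choice this package fixes and documents since the alternative (annual
deflation) differs only through within-year index drift.

Portfolio membership uses the cumulative-yield rule: species ranked by
multi-year summed yield, kept through the first species at which the
cumulative share reaches 90% (inclusive crossing, ties alphabetical).
The selected set is applied consistently to the harvest partition layer,
the species (biomass) layer, and every indicator, so that cross-layer
regressions compare like with like.

## Piecewise SEMs

Hypotheses linking the two layers are expressed as a DAG of linear
sub-models (`path_model()`, `fit_psem()`).  Sub-models are OLS, or — for
short autocorrelated annual series — generalized least squares with AR(1)
errors estimated by full maximum likelihood with a stationarity-
constrained autocorrelation (via `nlme::gls`); with only ~17 annual
observations, two-step feasible GLS is unstable, hence ML.  Inference
uses $t$-tests on $n-p$ residual degrees of freedom with the GLS
coefficient covariance.  Standardized coefficients are
$\hat\beta\,\mathrm{sd}(x)/\mathrm{sd}(y)$ computed on the *modeled*
scales: a sub-model declared with a log transform standardizes on the log
scale.

Goodness of fit is tested by directed separation: for every non-adjacent
ordered pair $(u,v)$ with $v$ endogenous and not an ancestor of $u$, the
model implies $u \perp v \mid \mathrm{pa}(v)\cup(\mathrm{pa}(u)\cap
\mathrm{an}(v))$; each claim is tested by adding $u$ to the conditional
regression for $v$ and reading its $p$-value, and the claims combine into
Fisher's $C=-2\sum\ln p_i \sim \chi^2_{2k}$.  Claim regressions inherit
the error structure declared for the dependent variable's sub-model —
a documented package choice, since published applications rarely state
how autocorrelation enters the claim tests.  Claims between two exogenous
variables are excluded (their joint distribution is not modeled).  The
basis-set construction is validated in the test suite against an
exhaustive graphical d-separation oracle (moralized ancestral graphs)
over all labelled DAGs with up to four nodes and batches of random
five-node DAGs.

Interannual trends (`fit_trend()`) are linear or quadratic ML fits with
iid, AR(1) or AR(2) errors; the quadratic stands in for the smoother
shapes used in exploratory work, since nothing downstream consumes more
than a trend's direction and significance.  The AR order is configured,
not selected automatically: "visual inspection of residuals" is not
reproducible.  Trend terms are flagged for display at $p<0.1$.

## The synthetic world

`scenario_preset()` encodes a seventeen-year, five-survey-month
(March/May/July/September/November) estuarine system with two regions'
worth of presets:

* `synchronous_null` — two equal species, identical seasonal phase, no
  closure: the all-synchronous baseline ($\phi\approx1$).
* `md_closure` — five stocks; the dominant, high-value stock (striped-
  bass-like, autumn-peaking, ~55% of landings) is closed March–May, and
  spring-peaking alternatives fill the window to a degree that varies
  between years.
* `va_compensation` — three stocks with a ~5-month offset between the
  dominant late-spring migrant and the autumn-peaking others:
  within-year compensation.
* `va_decline` — the same community with geometric interannual declines
  calibrated (by `decline_to_trend()`, exact root-finding on the trend
  recursion) so the period means of years 10–17 versus 1–9 fall by 92%,
  77% and 51%, concentrated in the dominant stock.

Mechanics: true biomass is a seasonal sinusoid
$b_0\,r^{t-1}(1+a\sin 2\pi(m-\varphi)/12)$ times mean-one lognormal
species-year effects (SD 0.35) whose logs share an annual environmental
factor (loading $\sqrt{0.5}$; the coastal migratory stock in `md_closure`
is unloaded, its dynamics being set outside the estuary) and whose
seasonal timing jitters between years (SD 0.75 months).  A stratified
random trawl survey (three depth strata, ten hauls per stratum-month)
observes catch as compound Poisson–gamma (Tweedie, $p=1.5$, $\varphi=2$)
around density × swept area, and a design-based stratified estimator
expands mean stratum densities by stratum areas.  Monthly fishing effort
is `base_effort` scaled by (open biomass)$^{0.5}$, shared among open
stocks as $(qBp)^{0.5}$ (moderate switching); harvest is catchability ×
share × effort × biomass under mean-one lognormal observation noise
(SD 0.25); closed species-months harvest exactly zero; values are harvest
× price and trips the rounded, jittered effort shares.

Calibration of the free parameters was done once, against the system the
presets emulate, not against any test threshold: per-species
catchabilities are solved (`calibrate_catchability()`) so baseline-world
annual landings match the observed regional magnitudes (without this,
effort switching concentrates >90% of landings on the dominant stock and
the 90% species rule degenerates to a single species); the dominant VA
stock starts ~10× the others, as a community whose dominant then loses
92% must; and the timing-jitter and shared-factor values were chosen so
the two cross-layer relationships the source system exhibits — a
closure-ratio → harvest-compensation relationship of $R^2\approx0.6$ and
a species→harvest compensation path of standardized strength ≈0.55 —
are approximately reproduced.  What a green mechanism test establishes is
therefore that the *estimators recover relationships of realistic
strength from realistically noisy panels*; it does not establish anything
about real landings data, and the generator deliberately omits features
of real systems (harvest→population feedback, spatial structure beyond
uniform density, price dynamics, reporting error structure) that could
weaken such relationships further.

## Numerical choices and limitations

* SDs equal to zero are detected at a relative $10^{-12}$ threshold, so
  exactly-compensating integer panels degenerate cleanly rather than
  returning astronomically large ratios.
* Claim $p$-values of exactly zero are clamped at $10^{-300}$ (with a
  warning) before entering $\ln p$.
* `to_panel()` refuses incomplete panels: a missing survey cruise must be
  handled upstream (interpolation is out of scope), and an absent row is
  never an implicit zero — but a recorded zero (a closed season) is data.
* Partial-month closures are month-resolved: a month counts as closed
  when ≥15 of its days are; only closures long enough to split the
  survey months feed the SHR, so this convention affects no computed
  index under the default calendars.
* Uncertainty in the biomass indices is not propagated into the
  partition (a known limitation of the approach this package
  implements); the stratified estimator's SEs are reported but unused
  downstream.
* The d-separation basis set assumes linear-Gaussian claim tests; the
  Fisher's C calibration demonstrated in the acceptance suite is under
  iid Gaussian noise at $n=17$.
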