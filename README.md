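# finstab

Stability–asynchrony partitioning for multispecies fishery harvest
portfolios and the ecological communities they draw on.

## The problem

When a regional fishing portfolio is spread across several stocks whose
harvests fluctuate out of phase within the year, total monthly harvest is
steadier than the average stock — a *portfolio effect*. `finstab`
quantifies that effect for monthly panels of biomass, harvest mass,
dockside value or fishing trips, and provides the downstream machinery
(annual indicators, piecewise structural equation models, trend models,
and a synthetic estuarine-fishery generator) needed to ask *why* harvest
asynchrony arises: natural compensatory migration, management closures, or
effort switching by fishers.

For a species × month matrix with per-species sample SDs σᵢ, means μᵢ,
and column-sum series with mean μ_R and SD σ_R:

- aggregate (portfolio/community) stability `S = μ_R / σ_R` (inverse CV);
- species-level stability `S̄ = μ_R / Σσᵢ` (inverse weighted-mean CV);
- asynchrony `ϕ = Σσᵢ / σ_R ≥ 1`, with ϕ = 1 under perfect synchrony;
- statistical averaging effect `SAE = Σσᵢ / √(Σσᵢ²) ∈ [1, √n]`;
- compensation effect `CPE = √(Σσᵢ²) / σ_R` (inverse square-rooted
  variance ratio; > 1 means negatively covarying stocks).

These satisfy the exact multiplicative decomposition `S = ϕ·S̄` and
`ϕ = SAE·CPE`, which the package verifies on every call.

Alongside the partition the package computes per region-year: the
seasonal harvest ratio (SHR) around a fishery closure, harvest-weighted
mean month of harvest, a trips-based effort index, portfolio yield and
value, and short (survey-month) and long (12-month) portfolio harvest and
value stabilities.  Piecewise SEMs over these annual series are fitted as
sets of linear sub-models (OLS or ML generalized least squares with AR(1)
errors), with overall fit tested by directed separation and Fisher's
`C = −2·Σ ln pᵢ ~ χ²(2k)`.

## Worked example

```r
library(finstab)

# A two-stock year: harvests partly out of phase
x <- rbind(A = c(4, 6), B = c(5, 4))
colnames(x) <- c(1, 2)
partition_stability(x, layer = "harvest")
#> Within-year stability-asynchrony partition (layer: harvest)
#>   n = 2 species, T = 2 months
#>  S_agg  S_bar    phi    SAE    CPE
#> 13.435  4.478  3.000  1.342  2.236
#>   identities: S_agg = phi * S_bar;  phi = SAE * CPE
```

Total harvest (9 then 10) is far steadier than the stocks individually:
aggregate stability 13.4 versus species-level 4.5, an asynchrony of
ϕ = 3.  Of that, SAE = 1.34 comes from independent-fluctuation averaging
and CPE = 2.24 from genuine compensation (A rises while B falls).

An end-to-end run on the built-in scenario emulating a
northern-estuary fishery with a spring closure of the dominant stock:

```r
res <- run_pipeline(list(scenario = "md_closure"), seed = 12,
                    out_dir = "run1")
summary(lm(cpe_harvest ~ shr, data = res$table))$r.squared
#> [1] 0.4255274
```

Years in which other stocks fill the closure window (high SHR) are years
of high harvest compensation — the closure, not community dynamics,
drives harvest asynchrony in this scenario.  The run directory contains
the simulated records, design-based biomass indices, the per-year
partition table, annual indicators, fitted SEM JSONs, trend fits, and a
manifest allowing byte-identical reruns.

## Acceptance script

`scripts/acceptance.R` recomputes from scratch, using only the installed
package: (t1) the asynchrony ϕ of a perfectly synchronous community built
from scalar multiples of one base monthly series, and (t2) the minimum of
ϕ over 10,000 random lognormal species × month panels.  Run it as:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
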