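# phenocirc

Estimating long-term shifts in flowering date from dated herbarium
specimens, for phenology researchers working with museum occurrence data —
particularly for tropical species whose flowering seasons can span the New
Year, where ordinary linear regression of day-of-year on year breaks down.

## The model

Collection dates become leap-scaled days-of-year and then angles,
θ = 2π·doy/365 − π ∈ (−π, π]. For each species the flowering angle is
regressed on collection year with a Bayesian circular GLM,

    θᵢ ~ VM(μᵢ, κ),   μᵢ = β₀ + 2·arctan(β₁·(xᵢ − x̄)),

a von Mises response with the inverse tan-half link, fitted by MCMC (Gibbs
for β₀ from its von Mises full conditional; random-walk Metropolis for β₁
and log κ; 4 chains × 2500 iterations after 200 burn-in, Gelman–Rubin R̂
per parameter). Posterior slopes convert to the field's shift metric,

    ΔDOY/decade = total shift in days / (span of years / 10),

with the total evaluated per posterior draw on the link scale. Around the
core regression the package provides: Darwin Core style occurrence reading
with date-quality filtering; the four dataset-construction rules (flowering
month cap with circular Dec–Jan adjacency, specimen minimum, year span or
calendar window, per-day cap) as six ready presets; Blomberg's K with a
permutation test for phylogenetic signal in the shifts (Grafen branch
lengths and near-zero branch repair included); and a synthetic record
generator with drifting von Mises flowering dates and uneven collection
effort, so the whole chain is testable without any data download.

## Worked example

Simulate one species drifting 3 days/decade later, fit it, and convert:

```r
library(phenocirc)

spec <- sim_species_spec("Demo species", mean_doy_at_ref = 180,
                         drift_days_per_decade = 3, kappa = 15,
                         records_per_year_rate = 4,
                         year_range = c(1940, 2000))
records <- simulate_records(sim_config(spec, seed = 7))
series  <- build_series(records, "Demo species")
fit     <- fit_circular_glm(series, circglm_config(seed = 3))
fit
#> Bayesian von Mises circular regression
#>   n = 288, years 1940-2000 (centred at 1968.0)
#>   beta0 (circular): -0.0517 rad (sd 0.0145)
#>   beta1 (link/yr):  0.00368 (sd 0.00043)
#>   kappa:            17.15
#>   rhat: beta0 1.000, beta1 1.000, kappa 1.000

shift_from_fit(fit, "Demo species")[, c("days_per_decade",
                                        "days_per_decade_sd", "direction")]
#>   days_per_decade days_per_decade_sd direction
#> 1        4.255277          0.4948315     later
```

288 simulated specimens over 61 years give a posterior mean slope of
0.0037 on the link scale — about 4.3 ± 0.5 days/decade later, i.e. a true
3 days/decade drift recovered within 3 posterior SDs. The published
conversion arithmetic is one call:

```r
rate_from_total(80.47, 57, display = TRUE)   # 14.1 days/decade
rate_from_total(17.15, 42, display = TRUE)   # 4.08
```

The full study-scale analysis lives in `analysis/01_simulate.R` …
`analysis/05_phylo_signal.R`: generate a 33-species cohort (23 drifting
later, 10 earlier, a 1914–1945 collection-effort dip), materialise the six
datasets, fit every species, summarise each dataset, and test phylogenetic
signal. Each stage writes its tables under `results/`.

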