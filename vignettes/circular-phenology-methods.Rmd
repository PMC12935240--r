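---
title: "Estimating flowering-phenology shifts from herbarium records: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating flowering-phenology shifts from herbarium records: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenocirc)
```

## The problem

Herbarium specimens carry a collection date, and for species with short,
annual flowering seasons a dated flowering specimen is a draw from the
species' flowering-time distribution in that year. Regressing collection
day-of-year on collection year therefore estimates how the mean flowering
date has moved over decades. Two features make this harder than an ordinary
regression:

* **The response is circular.** Some species flower across the New Year, so
  their dates cluster around the December–January boundary; a linear mean of
  day-of-year for such a species is meaningless. `phenocirc` maps dates to
  angles and models them with a von Mises distribution, the circular analog
  of the normal.
* **Collection effort is uneven.** Museum collections thin out in some
  periods (worldwide, collections dipped roughly 1914–1945), and several
  specimens may come from a single collecting day.

## Date handling

Dates become a leap-scaled day-of-year: the ordinal day (Jan 1 = 1), in
leap years multiplied by 365/366 so that a calendar position corresponds to
the same fraction of the year whether or not the year has 366 days, and the
output always lies in (0, 365]. Angles follow as

$$\theta = \frac{2\pi \cdot \mathrm{doy}}{365} - \pi \in (-\pi, \pi].$$

Dec 31 maps to $\pi$ in every year, and the map is a bijection inverted by
`radians_to_day()` (round-trip exact to 1e-9 in the tests). The leap rule
deserves a note: one could instead use a 366 denominator in the angle
formula for leap years. The two readings differ by less than 0.01 rad; the
multiplicative rescale was chosen because it keeps a single angle formula
for all years.

Records with a year but no month and day are dropped, not imputed: filling
in a mid-year day would drag circular means toward mid-year. Rows whose
`basisOfRecord` is not a preserved specimen are excluded, since the analysis
is about physical herbarium material. When a file carries both split
year/month/day columns and an ISO `eventDate`, the split columns win if the
two agree and the row is dropped (and logged) if they conflict.

## The regression model

For species $s$ with observations $(x_i, \theta_i)$ — collection year and
flowering angle — the model is

$$\theta_i \sim \mathrm{VM}(\mu_i, \kappa), \qquad
  \mu_i = \beta_0 + 2\arctan\!\big(\beta_1 (x_i - \bar{x})\big),$$

a circular GLM with the inverse tan-half link, which maps the real line
into $(\beta_0 - \pi, \beta_0 + \pi)$ so the mean direction can never wrap
past the antipode of the intercept. The predictor is centred at the mean
collection year for numerical stability; the centring constant is stored
with the fit. Each species is fitted separately.

**Priors.** Noninformative defaults: $\beta_0$ uniform on the circle,
$p(\beta_1) \propto 1$, $p(\kappa) \propto 1$ on $\kappa > 0$. The flat
slope prior is formally improper — as $|\beta_1| \to \infty$ the likelihood
plateaus rather than vanishing — but for any informative series the plateau
is exponentially far below the mode and finite chains never reach it; a
proper mean-zero Gaussian prior on $\beta_1$ is available through
`circglm_config(beta1_prior_sd = )` for pathological series.

**Sampling.** Defaults are 4 chains, 200 burn-in iterations and 2500
retained iterations per chain, seeded per chain as `seed + chain`. Within a
sweep:

* $\beta_0$ is Gibbs-sampled from its von Mises full conditional
  $\mathrm{VM}\!\big(\mathrm{atan2}(S, C),\, \kappa\sqrt{S^2+C^2}\big)$ with
  $S = \sum_i \sin r_i$, $C = \sum_i \cos r_i$,
  $r_i = \theta_i - 2\arctan(\beta_1(x_i - \bar x))$, using a Best–Fisher
  rejection sampler;
* $\beta_1$ and $\log\kappa$ move by random-walk Metropolis. Proposal
  scales start at $2.4/\sqrt{I}$ for the approximate Fisher information $I$
  at moment-based initial values and are adapted every 25 iterations during
  burn-in only (targeting 44% acceptance), so the post-burn-in kernel is a
  fixed, valid MCMC kernel.

Correctness is established behaviourally rather than by trusting the
sampler: the test suite compares the MCMC marginals on a 10-observation
series against a brute-force posterior evaluated on a dense
$120^3$ grid (total variation below 0.05 per marginal), and runs parameter
recovery and null-calibration studies described below. Convergence is
monitored by the Gelman–Rubin $\hat R$ across chains; fits with
$\hat R > 1.1$ on any parameter are flagged, not discarded.

**Summaries.** $\beta_0$ gets circular summaries (mean direction, circular
SD); $\beta_1$ and $\kappa$ get linear posterior means and SDs, the slope
SD being the per-species uncertainty measure carried into the output
tables.

## From slopes to days per decade

For each posterior draw the total change in mean direction across the
species' observed span is
$\Delta\theta = \mu(x_{\max}) - \mu(x_{\min})$, evaluated on the link scale
where no modular wrap is possible. The total shift in days is the posterior
mean of $\Delta\theta \times 365 / 2\pi$, and

$$\Delta\mathrm{DOY/decade} = \frac{\mathrm{total\ days}}
  {\mathrm{span\ years}/10}.$$

Averaging the per-draw totals (rather than converting the posterior-mean
slope) propagates slope uncertainty into the shift; with the odd, monotone
link the sign of the shift always equals the sign of the posterior-mean
slope. Positive means flowering later in the year. Exact zeros — not
attainable with continuous posteriors — would be excluded from both
direction tallies and reported separately. Display rounding is 3
significant figures for rates and 2 decimals for totals; files keep full
precision.

## Dataset construction

Four rules, combined into six presets (`table_criteria(1:6)`), decide which
species enter a dataset: a cap on the number of distinct calendar months
with flowering records (pooled over all years, and required to form one
contiguous circular block, December adjacent to January); a minimum
specimen count; either a minimum span of collection years or a calendar
window (collections from 1960 on, or before 1960), with counts and spans
recomputed on the windowed records; and optionally at most one specimen per
species per day, keeping the lexicographically smallest occurrence id so
dedup is deterministic. Months are pooled across years because the month
cap describes a property of the species' flowering season, not of any
single year. The presets are: (1) ≤4 months, ≥20 specimens, ≥29-year span;
(2) as 1 with ≤3 months; (3) as 1 with >50 specimens; (4) ≥20 specimens
from 1960 on; (5) ≥20 specimens before 1960; (6) as 1 plus the per-day cap.
Filtering is idempotent and monotone: tightening any threshold can only
remove species.

## Phylogenetic signal

Species-level shift magnitudes are tested for phylogenetic signal with
Blomberg's K:

$$K = \frac{\mathrm{MSE}_0/\mathrm{MSE}}
           {E[\mathrm{MSE}_0/\mathrm{MSE}]}, \qquad
  E[\mathrm{MSE}_0/\mathrm{MSE}] =
  \frac{\mathrm{tr}(V) - n/(\mathbf{1}^\top V^{-1}\mathbf{1})}{n-1},$$

with $V$ the Brownian-motion tip covariance (shared root-to-MRCA path
lengths), $\hat a$ the GLS mean, $\mathrm{MSE}_0$ the ordinary and
$\mathrm{MSE}$ the phylogenetically corrected mean squared error. $K = 1$
is the Brownian expectation — exactly 1 on a star phylogeny for any trait —
and $K$ is invariant to affine trait transforms and to global branch
rescaling (both tested to 1e-9). Significance comes from a one-sided
permutation test (high K = signal): trait values are shuffled across tips,
$p = (1 + \#\{K_{perm} \ge K_{obs}\})/(1 + n_{perm})$, so 1000 permutations
floor the p-value at 1/1001.

Trees without branch lengths get Grafen lengths (node height proportional
to descendant tips minus one, root height 1); unrooted trees are
midpoint-rooted first, with a message. Near-zero branches are raised to a
small constant, by default $10^{-6}$ times the tree height — large enough
to keep $V$ invertible, small enough to leave K unchanged at reporting
precision.

## The synthetic study

`simulate_records()` generates the data structure the analysis assumes:
per species, yearly collection counts are Poisson with an effort-weighted
rate, and each record's angle is drawn from
$\mathrm{VM}\!\big(\mu(\mathrm{year}), \kappa\big)$ where $\mu$ drifts
linearly in days per decade, anchored at the midpoint of the year range (so
the intercept stays interpretable whatever the drift). Angles convert back
to valid Gregorian dates — leap days appear only in leap years, and a
late-December mean with moderate concentration legitimately yields January
records, exercising the circular model's reason for existing. Each species
draws from its own RNG substream derived from the master seed by a stable
label hash, so adding a species leaves the others' records byte-identical.

The default study configuration in `analysis/01_simulate.R` and the
acceptance script uses 33 species, 23 drifting later and 10 earlier, drift
magnitudes uniform on 1–5 days/decade, $\kappa = 25$ (a flowering SD of
about 12 days, i.e. a 2–3-month season), 3.5 collections/year over
1920–2000, and a 1914–1945 effort dip with multiplier 0.5. The dip depth is
a user-set choice — the historical record shows a dip but not its size —
and 0.5 is used throughout as a plausible halving. The drift floor of 1
day/decade makes every simulated direction detectable at these sample
sizes, which is what the direction-split check needs; magnitudes below
posterior noise would make the split a coin flip on those species.

What the generator does **not** emulate: spatial structure and collector
route bias, within-year seasonality of collecting effort, phenology driven
by climate covariates rather than a linear trend, multiple flowering peaks
per year, and identification error. Passing tests therefore show that the
estimator recovers the model's own generative process under realistic
sample sizes and effort gaps — not that real GBIF data satisfy that
process.

## Verification sizes and numerical choices

The test suite runs, among others: a 50-species recovery study (drifts
±6 days/decade, $\kappa = 15$, 150–300 records over a 60-year span)
requiring the posterior mean within 3 posterior SDs of truth for at least
47 species and correct signs for all drifts ≥2 days/decade; a 100-species
null study requiring mean $|\Delta\mathrm{DOY/decade}| < 0.7$ and ≥90%
coverage of zero by the 95% slope intervals; 200 Brownian simulations on a
fixed 33-tip Grafen tree with mean K in [0.85, 1.15]; and a
Kolmogorov–Smirnov check that permutation p-values are uniform under the
null. Study-scale fits in the tests use 2 chains × 1500 iterations — the
data conditions, not the chain budget, are what those checks constrain —
while all defaults remain 4 × 2500.

Numerical edge cases: the log-Bessel term uses the exponentially scaled
`besselI` so likelihoods stay finite at $\kappa$ in the thousands; the
von Mises sampler falls back to the circular uniform below
$\kappa = 10^{-8}$; series with fewer than 3 records or a single distinct
year are rejected ("no temporal contrast"); a singular phylogenetic
covariance points the user to the branch repair; a constant trait yields
$p = 1$ with a warning.

## Limitations

Per-species fits ignore shared year effects across species at a site;
shifts are linear trends, so accelerating change is averaged; the
days-per-decade conversion uses each species' own observed span, so spans
differing by an order of magnitude (42 vs 229 years here) average shifts
over very different windows; and the permutation test addresses only
exchangeability, not uncertainty in the tree or in the trait estimates
themselves.
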