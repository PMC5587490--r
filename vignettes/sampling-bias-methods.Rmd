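---
title: "Quantifying sampling bias and inventory completeness in pentad atlases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sampling bias and inventory completeness in pentad atlases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlaseffort)
```

# The problem

Checklist atlases ask volunteers to survey a grid cell — a pentad, 5
arc-minutes on a side — for a fixed minimum effort and report every
species encountered. Coverage maps of such projects share a signature:
effort concentrates around cities, birding destinations, roads and
reserves, and decays outward. Two questions follow. *Where* is the
data thin relative to the environmental variety of the region, and
*how complete* is the species inventory of each environment at the
current effort? This package answers both with a pipeline of four
stages: environmental zonation, representativeness testing, an effort
regression, and accumulation-curve completeness estimation, all
validated on a synthetic atlas with known truth.

# Environmental zonation

The three climate variables (mean annual precipitation in mm/yr, mean
summer and winter temperature in °C) are reduced by PCA **on the
correlation matrix**. Covariance-matrix PCA is meaningless here — the
precipitation variance in mm² swamps the temperature variances — and
standardization also buys unit invariance, which the test suite
asserts (multiplying precipitation by 1000 changes nothing). Each
component is sign-fixed so its precipitation loading is non-negative;
PC1 then runs from hot-and-dry (low) to moist-and-mild (high).

PC1 scores are binned into `n_classes = 10` **equal-width** classes
over the observed score range, with the top edge closed. Equal width
rather than quantiles is deliberate: climate classes should represent
equal slices of the climate gradient, not equal numbers of pentads —
unequal class sizes are exactly what the representativeness analysis
is about.

Each pentad takes the biome covering its largest area fraction (ties
go to the lexicographically smallest label, with a warning). Biomes
too marginal to analyze — in `zonate_landscape()`, any biome whose
total expected frequency at the stricter threshold falls below the
pooling minimum — are dissolved: each of their pentads takes the modal
biome of its queen-neighbourhood (8 adjacent cells) among
non-dissolved pentads, iterated to a fixed point, with a
nearest-pentad fallback for isolated islands.

Zones are the occupied biome × class combinations, pooled within each
biome until every zone's expected frequency at the stricter sampling
threshold reaches `min_expected = 5`. The value 5 is Cochran's rule
for the chi-square family: an "expected frequency above 5 percent"
reading would be unattainable with dozens of cells, so the count
interpretation is used. The zone with the smallest expected frequency
merges with the zone of the nearest climate class in the same biome
(ties toward the lower class), which reproduces the familiar pooled
labels such as `Fynbos:7+8`. The minimum expected frequency is
monotone non-decreasing over merge iterations, so pooling terminates;
a biome that cannot reach the threshold even fully pooled raises an
error directing the user to coarser classes.

# Representativeness

For thresholds of ≥1 and ≥10 lists per pentad (total coverage versus
the repeat visits needed to separate non-detection from absence), the
observed number of sampled pentads per zone is compared with the
size-proportional expectation

```
expected = (zone pentads / total pentads) × total sampled pentads,
```

whose sum equals the sampled total by construction; deficits
(observed − expected) therefore sum to zero, an identity asserted on
every run. Evenness is tested with the goodness-of-fit G-test,
`G = 2 Σ O ln(O/E)` with `0 ln 0 = 0`, on `k − 1` degrees of freedom,
overall and per biome (expecteds recomputed within the biome). No
Williams correction is applied; per-biome p-values are reported
unadjusted by default, with an optional Holm flag. The test's
multinomial null is exactly "each sampled pentad falls in a zone with
probability proportional to the zone's size"; the suite verifies a
5 ± 1.5 percent rejection rate at α = 0.05 under that null. Zones are
ranked by deficit at each threshold to direct future effort.

# The effort model

Visits per pentad are modelled as quasi-Poisson with log link:
predictors are the natural log of hub distance (hub pentads themselves
are excluded, so the distance is positive — they are the effort
sources, not samples of it), road distance in km, the three cover
fractions, and the three climate variables standardized within the
fitted group so coefficients are per-SD. Fitting is iteratively
reweighted least squares (`glm`), convergence at relative deviance
change 1e-10 or 100 iterations; the Pearson χ²/df dispersion scales
the standard errors, and t and p values use the residual degrees of
freedom (the df convention differs slightly from quasi-likelihood
mixed-model output; with thousands of pentads the difference is
negligible). VIFs are computed from each predictor's R² on the others.

A spatially correlated random effect is **deliberately not fitted**.
Instead the package reports a permutation Moran's I on the Pearson
residuals (inverse-distance weights, row-standardized, upper-tail p
from residual permutation). Point estimates are ordinary GLM
estimates; when Moran's I flags strong residual autocorrelation, the
quasi-Poisson standard errors should be read as optimistic.

# Accumulation curves and completeness

The accumulation unit is the pentad: a pentad contains a species if
any of its lists records it, and separate incidence matrices are built
at each threshold. The expected richness among `n` of `N` pentads has
the closed form

```
S(n) = Σ_j [ 1 − C(N − f_j, n) / C(N, n) ],
```

the exact mean over all `C(N, n)` subsets, evaluated with log-gamma
arithmetic so large `N` is safe. The suite checks it against the full
combinatorial enumeration for `N ≤ 10` at 1e-10, and against an
independent implementation. The traditional smoothed curve — the mean
over 1,000 random pentad orderings — is provided as a seeded
cross-check and agrees with the exact curve within Monte-Carlo error.

Three asymptotic models are fitted by Levenberg–Marquardt:

* Lomolino: `S = Asym / (1 + slope^log10(xmid/n))` — log base 10 in
  the exponent by convention; other bases only rescale `slope`.
* Clench: `S = Asym · n / (B + n)`.
* Weibull: `S = Asym · (1 − exp(−(n/scale)^shape))`.

Starts are `Asym = 1.1 · S_obs`, the half-richness `n` by
interpolation for `xmid`/`B`/`scale`, and a small grid of shape starts
(`slope ∈ {2, 5, 15, 40}`, `shape ∈ {1, 0.5, 2}`), keeping the
lowest-RSS fit: the sigmoidal models have a degenerate optimum
(`xmid → 0` flattens the curve at `Asym`) that a single start can fall
into. Convergence tolerance is 1e-8 with at most 500 iterations; fits
that fail are flagged, not fatal, and flagged zones rank last with
`NA` completeness. A converged asymptote materially below `S_obs`
(beyond 0.1 percent) triggers a warning. Completeness is
`100 · S_obs / S_est`, and zones are ranked least-complete first.
Curve fitting is unweighted: rarefaction variances shrink toward both
endpoints, and weighting schemes change completeness by far less than
the model choice does.

On Lomolino-shaped curves the Lomolino model attains the lowest RSS
essentially whenever the curve's own smoothness dominates the noise; a
flexible Weibull can shadow a Lomolino shape to within a fraction of a
species per point, so under heavy artificial noise the best-RSS winner
degenerates to a coin flip. The model-comparison check therefore uses
small perturbations (sd 0.5 species) of varied Lomolino curves — the
realistic regime, since fitted rarefaction curves are smooth averages
— while asymptote-recovery robustness is tested separately at sd 2.

# The synthetic atlas

The generator emulates the statistical structure the pipeline assumes,
not any particular geography:

* **Landscape** — a rectangular pentad grid (default 40 × 40 starting
  at 26°S 22°E); climate surfaces are a linear hot-dry-NW to
  moist-mild-SE gradient plus a low-order sinusoidal field
  (deterministic per seed; amplitude 0 gives exactly linear surfaces).
  A Gaussian-process simulation would add nothing the pipeline is
  sensitive to. Biomes are a nearest-seed partition with up to seven
  labels; cover fields are smooth functions of hub distance (urban),
  reserve centres (protected) and precipitation (cultivated).
* **Effort** — visits per pentad are Poisson with
  `log λ = b0 + b_loghub·log(d_hub) + b_road·d_road + b_prot·prot +
  b_urban·urban + b_cult·cult + climate terms`, the same family the
  analysis fits. Defaults (`b0 = 3.2`, `b_loghub = −0.45`,
  `b_road = −0.03`, `b_prot = 1.5`, `b_urban = 2.0`, `b_cult = 0.3`,
  climate ±0.1–0.15; 4 hubs, 16 road waypoints) were fixed once to
  match a mature but uneven national atlas: roughly three quarters of
  pentads get at least one list while only a few percent get ten or
  more.
* **Community** — each zone holds a species pool (default lognormal
  around 90 species, sd 0.25 on the log scale) with a configurable
  widespread fraction (default 0.2) shared across all pools; every
  pool species occupies each zone pentad independently with
  probability 0.35.
* **Detection** — each visit detects each occupying species
  independently with `p_det = 0.6` (a per-species vector is
  accepted); there are **no false positives**, mirroring the vetting
  step of real atlas projects, and lists that detect nothing are
  dropped (a submitted list always has a species) but counted in the
  truth record.

Every stage takes an explicit seed and `simulate_atlas()` derives
stage seeds from one master seed, so a run is reproducible
bit-for-bit; the recorded truth (effort coefficients, per-zone
richness, occupancy, detectability, dropped-list count) supports
parameter-recovery tests: on a 60 × 60 grid every effort coefficient
is recovered within 3 SE and 95% CIs cover the truth at nominal rate
over 200 replicates.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: rare-species abundance
tails (occupancy is homogeneous within a pool, so simulated
inventories saturate faster than real ones and default completeness
values cluster near 100 at the loose threshold), observer skill
heterogeneity, seasonal turnover, spatially correlated residual effort
beyond the covariates, and within-pentad habitat coverage differences
between visits (detection is i.i.d. across visits).

# Conventions and edge cases

* Pentad codes name the **north-west corner** (`3355_1825` = 33°55′S,
  18°25′E); cells are half-open toward the south-east so every
  coordinate belongs to exactly one pentad; midpoints sit 2.5′
  south-east of the corner. Longitude fields of four or five digits
  are accepted; four digits are written.
* Distances are haversine on a 6371.0 km sphere. Roads are densified
  polyline vertices (≤1 km spacing expected), so point-to-vertex
  minima err by at most half the spacing; an ellipsoid or true
  segment projection would change log-distance predictors by well
  under a percent. Road distance is measured from the pentad
  midpoint, like hub distance.
* Readers reject invalid rows (duplicate visit ids, empty species
  lists, fractions outside [0, 1], duplicate pentads) with the row
  identified, rather than coercing.
* Degenerate inputs have defined behaviour: constant climate
  variables, all-equal PC1 scores, all-zero biome fractions, empty
  landmark sets and constant Moran residuals each produce a specific
  error or `NA`-with-reason, exercised in the suite.

# Problem sizes

The shipped tests run the pipeline on 18–20-pentad-square grids, the
coefficient-recovery study on a 60 × 60 grid with 200 replicates, the
rarefaction oracle on matrices up to N = 10 (exhaustive) and N = 40
(1,000 permutations), the G-test calibration on 2,000 null tables and
the asymptote-recovery study on 100 noisy 200-point curves — sizes at
which every Monte-Carlo tolerance above is meaningful while the whole
suite completes in about a minute.
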