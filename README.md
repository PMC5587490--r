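# atlaseffort

Volunteer bird atlases cover huge regions with checklist surveys of
5-arc-minute × 5-arc-minute grid cells ("pentads"), but the effort is
anything but even: observers cluster near cities, birding hotspots,
roads and reserves, so some environments are sampled intensively while
others are barely touched. `atlaseffort` quantifies that bias and its
consequences for how completely each environment's avifauna has been
inventoried. It is aimed at atlas coordinators deciding where to send
volunteers next, and at analysts who need to know how far the data can
be trusted across environmental gradients.

## What it computes

Given a checklist table (one row per visit: pentad, visit id, species
list) and per-pentad covariates (climate means, protected / urban /
cultivated cover fractions, biome cover fractions, distances to
sampling hubs and major roads), the package:

1. **Stratifies the region into environmental zones.** The three
   climate variables are reduced by a correlation-matrix PCA; PC1
   scores are cut into ten equal-width histogram classes (hot and dry
   at class 1 to moist and mild at class 10); each pentad takes its
   dominant biome; the biome × class combinations are pooled within
   biomes until every zone's expected frequency in the G-test is at
   least 5 (Cochran's rule). Pooled zones carry ids like `Fynbos:7+8`.
2. **Tests representativeness.** For each zone it counts pentads with
   ≥1 list and with ≥10 lists, computes size-proportional expected
   frequencies

   `expected = (zone pentads / total pentads) × total sampled pentads`,

   runs goodness-of-fit G-tests (`G = 2 Σ O ln(O/E)`, df = zones − 1,
   overall and per biome), and ranks zones by the observed − expected
   deficit.
3. **Models effort.** Visits per pentad are regressed on
   log hub distance, road distance, cover fractions and standardized
   climate in a quasi-Poisson GLM (per province analogue when a
   grouping is supplied), with VIF collinearity diagnostics and a
   permutation Moran's I test on the Pearson residuals.
4. **Estimates inventory completeness.** Per zone and threshold it
   builds the pentad × species incidence matrix, computes the exact
   (Mao Tau) sample-based rarefaction curve
   `S(n) = Σ_j [1 − C(N−f_j, n)/C(N, n)]`
   (the 1000-run permutation average is available as a cross-check),
   fits the asymptotic Lomolino `S(n) = Asym / (1 + slope^log10(xmid/n))`,
   Clench and Weibull models by Levenberg–Marquardt, and reports
   completeness `100 · S_obs / S_est` with zones ranked least-complete
   first.

A fully seeded synthetic-atlas generator (`simulate_atlas()`) creates
landscapes, biased effort, zone-structured communities and imperfect
detection with all ground truth recorded, so every estimator can be
validated against known parameters.

## Worked example

```r
library(atlaseffort)
bundle <- run_pipeline(pipeline_config(seed = 1))
summarize_report(bundle)
```

```
71.4% of pentads sampled at threshold >=1 lists (1143 of 1600)
  evenness G-test: G = 92.428, df = 7, p = 3.921e-17
  most oversampled: AlbanyThicket:6+7+8+9 (+63.7), Grassland:5+6+7+8 (+31.7), ...
  most undersampled: ..., SucculentKaroo:7+8+9+10 (-55.0), SucculentKaroo:5+6 (-68.9)
4.2% of pentads sampled at threshold >=10 lists (67 of 1600)
  evenness G-test: G = 100.671, df = 7, p = 7.839e-19
  ...
  least complete inventories: NamaKaroo:8+9+10 (98.9%), ...
```

About 71% of the 1,600 simulated pentads have at least one checklist
but only ~4% have ten or more; the G-tests reject even representation
of the environmental zones at both intensities (the arid
Succulent-Karoo zones carry the largest sampling deficits), and the
Lomolino asymptotes show the repeatedly-sampled subset still misses a
little of the Nama-Karoo richness. The fitted effort model recovers
the generator's coefficients:

```r
bundle$effort_fits$fit
#> <effort_fit> quasi-Poisson, dispersion = 1.057, df = 1587
#>                 coef     se        t      p
#> log_dist_hub -0.4977 0.0340 -14.6239 0.0000   (truth -0.45)
#> dist_road    -0.0296 0.0011 -26.6312 0.0000   (truth -0.03)
#> protected     1.2062 0.0929  12.9835 0.0000   (truth  1.50)
#> urban         1.8995 0.1684  11.2778 0.0000   (truth  2.00)
```

Effort decays with hub and road distance and rises with protected and
urban cover — the signature pattern of volunteer atlas data.

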