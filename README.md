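# plotcarbon

Quadrat-scale analysis of how fine-scale environment, functional
dominance and functional diversity relate to tree aboveground carbon
storage in large forest dynamics plots — plus a seeded synthetic-plot
generator with known ground truth, so that every stage of the pipeline is
verifiable without access to a real census.

**Who it is for.** Community ecologists and ecosystem scientists working
with CTFS-style stem-mapped plots (all stems with DBH ≥ 1 cm mapped and
identified on a 20 m quadrat grid) who want a reproducible route from the
raw census tables to the standard statistical battery: correlation
tables, stepwise regressions, variance partitioning and recursive path
models.

## What it computes

For each 20 m × 20 m quadrat *q* (N = 500 in the canonical
400 m × 500 m plot):

- **Terrain** — altitude = mean of the quadrat's four corner elevations;
  convexity = focal altitude − mean altitude of the 8 neighbouring
  quadrats (edge quadrats: centre-point altitude − focal altitude, with a
  documented reduced-neighbour fallback).
- **Soil fertility** — the nine soil properties (total and available N,
  P, K; organic matter; water content; pH) are interpolated from point
  samples to quadrat centres by ordinary kriging (WLS-fitted spherical or
  exponential variogram), then reduced by PCA on the correlation matrix
  to a fertility axis **PC1**, sign-anchored to increase with fertility.
- **Functional dominance** — community-weighted means
  CWM = Σⱼ aⱼxⱼ / Σⱼ aⱼ of LA, SLA, LDMC, WD and maximum DBH, with stem
  counts aⱼ as weights.
- **Functional diversity** — functional dispersion
  FDis = Σⱼ aⱼzⱼ / Σⱼ aⱼ, where zⱼ is the distance of species *j* to the
  abundance-weighted trait centroid cᵢ = Σⱼ aⱼxᵢⱼ / Σⱼ aⱼ; per trait and
  multivariate (pool-z-scored trait space).
- **Carbon** — per-stem AGB (kg) from the moist-forest allometry
  AGB = WD·exp(−1.499 + 2.148 ln D + 0.207 (ln D)² − 0.0281 (ln D)³),
  summed per quadrat and converted to Mg C ha⁻¹ with carbon fraction 0.5.
- **Statistics** — Pearson correlation tables with exact t-distribution
  p-values; bidirectional AIC-stepwise OLS; LMG hierarchical partitioning
  of R² (exact subset enumeration, ≤ 12 regressors); recursive path
  (SEM) models estimated by per-equation OLS on z-scored data, with
  χ² = (N−1)·F fit statistics, df = p(p+1)/2 − t, AIC = χ² + 2t, and
  stepwise pruning of non-significant paths.

## Worked example

```r
library(plotcarbon)

# simulate the default synthetic world (400 x 500 m, 92 species, ~80k
# stems, habitat filtering: high-WD species on convex sites, high-SLA
# species on fertile sites) and run the whole pipeline
res <- run_pipeline(list(simulate = list(), seed = 42))

qf <- res$quadrat_frame
mean(qf$c_storage)          # 224.74 Mg C ha^-1 (plot mean)
range(qf$c_storage)         # 27.0 .. 1205.8 across quadrats
```

Selected correlations with carbon storage (`res$analysis$correlations_c`):

```
         var1          r            p stars
    convexity  0.4323849 3.402849e-24   ***
     soil_pc1 -0.1877121 2.394984e-05   ***
       wd_cwm  0.5662727 9.709968e-44   ***
 max_dbh_fdis  0.5867941 1.374261e-47   ***
```

Convex (ridge-top) quadrats store more carbon, as planted in the
generator through the wood-density habitat effect; fertile quadrats
slightly less.  The pruned functional-dominance path model:

```
print(res$analysis$sem_dominance$fit)
path_fit: chi^2 = 1.105, N = 500, d.f. = 3, P = 0.776, AIC = 37.11
      from        to coefficient         p
  soil_pc1    la_cwm       0.765  2.48e-97
 convexity  ldmc_cwm       0.462  1.46e-76
  soil_pc1  ldmc_cwm      -0.726 7.70e-136
 convexity   sla_cwm      -0.313  4.66e-44
  soil_pc1   sla_cwm       0.814 1.03e-157
 convexity c_storage       0.251  8.41e-08
    la_cwm c_storage       0.375  2.36e-07
   sla_cwm c_storage      -0.545  4.58e-12
```

and the LMG decomposition of the all-variables stepwise model
(`res$analysis$importance`): R² = 0.456 split into dominance 0.270,
diversity 0.174, environment 0.013 for this realization.

The command-line interface mirrors the R API:

```sh
inst/cli/plotcarbon simulate --config cfg.yaml --seed 7 --out simdir
inst/cli/plotcarbon run-all  --config cfg.yaml
```

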