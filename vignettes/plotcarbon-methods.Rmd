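---
title: "Methods: from stem map to carbon, and what the synthetic plot does and does not test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from stem map to carbon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`plotcarbon` operationalises a quadrat-scale analysis chain for
stem-mapped forest dynamics plots.  The unit of analysis is the
20 m × 20 m quadrat; every derived quantity is a column of one
`quadrat_frame`, and the statistical layer works on that frame alone.
This vignette records the modelling choices, the tunable parameters, the
numerical conventions, and — most importantly — what a passing test
suite does and does not establish.

## Geometry

Coordinates are 0-based and half-open (`0 ≤ x < width`), quadrat cells
are `[k·s, (k+1)·s)`, and the linear quadrat id is `qx + n_qx·qy`.  The
half-open convention is not dictated by any field standard; it was
chosen because it makes floor-division assignment total and unambiguous
at cell boundaries.  Plot dimensions that are not exact multiples of the
quadrat size raise an error rather than silently truncating.

## Terrain

Quadrat altitude is the mean of the four corner elevations.  Convexity
of an interior quadrat is its altitude minus the mean altitude of its 8
neighbours.  For edge and corner quadrats the rule is the centre-point
altitude minus the focal altitude — but a corner-only elevation lattice
*cannot supply* a centre altitude: the bilinear interpolation of four
corners equals their mean, which would make edge convexity identically
zero.  We therefore accept an optional measured/generated centre-altitude
input (the synthetic terrain always provides one, evaluated from the same
analytic surface as the corners) and fall back to a reduced-neighbour
rule (focal minus mean of the existing 3–5 neighbours) when centres are
absent.  Which rule was used is flagged per quadrat in `edge_rule`; how a
real survey obtained edge centre points is not something we guess at.

Useful invariants, all tested: convexity is invariant under adding a
constant to all elevations, equivariant under scaling, and identically
zero (interior) on any plane.

## Soil interpolation and the fertility axis

Each of the nine soil properties is interpolated to quadrat centres by
ordinary kriging: method-of-moments semivariances in 15 equal-width lag
bins (to half the maximum pairwise distance, both configurable), a
weighted-least-squares model fit with pair-count weights, and the global
ordinary-kriging system with the unit-sum constraint via a Lagrange
multiplier.  Choices worth recording:

* **Family**: spherical with nugget by default, exponential available.
  The source methodology names only "ordinary kriging"; spherical is the
  workhorse for soil properties.
* **Scaling inside the fit**: semivariances and lags are normalised to
  O(1) before optimisation (L-BFGS-B, Nelder–Mead fallback) — nutrient
  properties have sills around 10⁻⁶ in squared natural units and the
  optimiser fails on them otherwise.
* **Flat variograms** (no resolvable spatial structure) pin the range at
  its upper bound and warn rather than error.
* **Degenerate inputs**: duplicate sample locations are averaged with a
  warning (they make the kriging matrix singular); a target coincident
  with a sample reproduces the sample value exactly (tested).
* **PCA** is computed on z-scored variables (correlation matrix) because
  the nine properties have incommensurable units.  PC1's sign is
  anchored so the mean loading of total N, organic matter and water
  content is positive; "higher PC1 = more fertile" is then deterministic.

The sample-size precondition is 2 (hard error) with a warning below 10;
the original contract said 10, but the package's own worked arithmetic
example (two samples, values 0 and 2, one bin, semivariance 2) requires
accepting tiny inputs, so the hard floor is the mathematical minimum.

## Functional dominance and dispersion

CWM and FDis use stem counts as weights — explicitly *not* basal area or
biomass, which would be circular with the carbon response.  FDis is the
abundance-weighted mean Euclidean distance of species to the
abundance-weighted centroid.  For multivariate FDis the five traits are
z-scored over the *species pool* (every species in the trait table), not
per quadrat, so all quadrats share one trait space; a range-scaled
(Gower-style) option is provided for comparison.  The pool-z-score +
Euclidean choice is a deliberate, documented simplification of the
Gower + PCoA route used by the FD literature: with five all-numeric
traits the two spaces are monotone-equivalent and the simpler one is
exactly testable against a hand-written double loop.  A trait with zero
pool variance contributes zero spread (not NaN).

Species missing from the trait table are excluded from CWM/FDis but
retained for carbon (below), mirroring the common situation where traits
are measured for the most abundant species only.  A quadrat with no
trait-covered stems gets NA and is dropped casewise by the statistical
layer.

## Carbon

Per-stem AGB uses the moist-forest DBH + wood-density allometry (in kg,
DBH in cm, WD in g cm⁻³); per-quadrat carbon is
`Σ AGB × fraction / 1000 / area_ha`, i.e. `kg × 0.5 × 0.025` for 20 m
quadrats.  The carbon fraction 0.5 is the convention of the C-storage
methodology the allometry is usually paired with, and is a config
parameter.  Stems of species without measured WD get the plot-level
stem-abundance-weighted mean WD (toggleable; disabling imputation makes
such species a hard error listing them).  Each census record is treated
as one stem; multi-stem individuals are out of scope.

## The statistical layer

* **Correlations**: Pearson r with two-sided p from the exact t
  distribution on N−2 df; stars at 0.05/0.01/0.001.
* **Stepwise regression**: both directions, AIC (k = 2), from the
  intercept-only model — the direction/criterion pair was an open choice
  and is recorded here; ties resolve toward the smaller model through
  R's `step` ordering.  Note a consequence, verified in the tests: with
  AIC entry, a pure-noise candidate enters with probability ≈ 0.157, so
  "null data give exactly the intercept-only model" is *false* for
  several candidates; what holds (and is tested) is that ≥ 90% of null
  fits are approximately intercept-only (adjusted R² < 0.02, ≤ 2
  spurious regressors).
* **LMG partitioning**: exact subset enumeration (2ᵖ R² evaluations from
  the covariance matrix), refusing p > 12; shares sum to the full-model
  R² to 10⁻¹⁰ and are order-invariant, both asserted.
* **Path models**: recursive (acyclic) observed-variable models,
  estimated equation-by-equation by OLS on z-scored data, which is
  ML-equivalent for recursive models with independent errors; the
  reported coefficients are therefore standardized.  Exogenous variables
  carry free variances/covariances; endogenous error variances are free;
  correlated errors may be declared for endogenous pairs (the default
  pipeline SEMs give the three leaf-trait mediators correlated errors).
  Fit: Σ̂ = (I−B)⁻¹Ψ(I−B)⁻ᵀ,
  F = ln|Σ̂| − ln|S| + tr(SΣ̂⁻¹) − p, χ² = (N−1)F,
  df = p(p+1)/2 − t, AIC = χ² + 2t.  These conventions reproduce both
  published fit summaries they were calibrated against (χ² 0.23/df 3 →
  AIC 36.23, P 0.97; χ² 2.69/df 3 → AIC 38.69, P 0.44) and give χ² = 0,
  AIC = 2t for saturated models to machine precision.
  **Pruning** removes the single worst path with p ≥ α (default 0.05)
  and refits until all retained paths are significant, logging the
  trace.

# The synthetic world

The generator's defaults state one fixed world, emulating the canonical
20-ha plot; they were chosen once, for realism, and are not tuned to
tests:

| parameter | default | why |
|---|---|---|
| plot | 400 × 500 m, 20 m quadrats | the canonical 500-quadrat layout |
| elevation | 230–470 m, 3 Gaussian hills + smooth bumps | the published relief range |
| soil design | 30 m lattice + 2 satellites at {2, 5, 15} m | the published sampling design |
| soil structure | one latent fertility field, loadings +0.6…0.85 (pH −0.6) | gives soil PCA a planted one-factor structure to recover |
| species pool | 92, multivariate-lognormal traits | the published common-species count; leaf-economics trade-offs (corr(SLA, LDMC) = −0.7 on log scale) |
| occupancy | logistic in z(convexity), z(fertility); β·z(log WD) and β·z(log SLA) | habitat filtering with known sign structure |
| abundance | occupied cells get 1 + Poisson(λⱼ), λⱼ lognormal | ~80k stems, matching the census magnitude |
| DBH | Weibull (shape 0.8, scale 0.10·maxDBHⱼ), truncated [1, maxDBHⱼ] | plot mean C ≈ 110 Mg C ha⁻¹, quadrat range ≈ 25–400 — old-growth magnitude; truncation ties the stem map to the max-DBH trait |

Every stage is deterministic under the master seed (stage seeds are
small fixed offsets).  Trait correlations are specified on the log scale
(Gaussian copula), so configured values are exact there and attenuated
on the raw scale; the recovery test asserts on log traits.

**What the synthetic world does not emulate** — and hence what a green
suite does *not* establish about real forests: spatial point-process
structure within quadrats (clustering, dispersal limitation),
demographic dynamics and gap disturbance, measurement error in traits
and DBH, non-stationary or anisotropic soils, and any resemblance of the
*numeric* coefficients to a particular real plot.  The published
data-dependent results (correlation tables, regression coefficients,
R² = 0.34/0.32, mean C = 103.19 Mg C ha⁻¹) depend on an undeposited
census and are deliberately not targets; only the self-contained worked
values (grid count, χ²/AIC/P conventions) are.

# Design of the stochastic acceptance checks

* **Variogram recovery** ("within 20% at dense sampling"): exact
  Gaussian-field draws from the target model (nugget 0.1, sill 1.0,
  range 60) on 500 base points + 1500 satellite close pairs in a 600 m
  square, 50 bins to lag 150; the comparison is on the mean of 40
  replicate fits.  Single realizations are *not* expected to be within
  20%: a 600 m domain holds only ~100 independent correlation ranges, so
  per-fit sills scatter ±10% and nuggets ±35%; the close-pair design was
  chosen (before freezing expected values) because equal-width bins plus
  pair-count weights otherwise leave the nugget under-identified.
* **Path-coefficient recovery** ("±0.07 in ≥ 95%"): a fully standardized
  recursive truth (every variable unit-variance, so OLS-on-z-scores
  estimates the stated coefficients without rescaling).  Effect sizes
  were set by an a-priori power analysis so that ±0.07 ≈ 2.4 asymptotic
  SEs at N = 500 — the criterion then tests estimator correctness rather
  than the weather; with weak signals the same criterion is
  mathematically unattainable for *any* unbiased estimator (±0.07 ≈
  1.7 SE ⇒ ~91% coverage), which is a property of the design, not of the
  code.
* **Habitat-sign recovery**: 100 full default-size plots; the planted
  positive β on wood density (convexity) and SLA (fertility) must yield
  positive CWM–environment correlations; observed r ≈ 0.8–0.9.
* **Null configuration**: β = 0 and independent traits drive the same
  correlations to |mean r| < 0.02 over 60 replicates with ≈ the nominal
  5% significant at α = 0.05 — the pipeline's type-I check.

# Known limitations

Kriging is global (all samples); a max-neighbour option would be needed
beyond ~5k samples.  LMG is exact-enumeration only (≤ 12 regressors).
The SEM layer handles observed variables only — no latent constructs, no
RMSEA/CFI, no spatial autocorrelation correction of p-values (the
upstream methodology performs none either).  The satellite soil points
are clipped to the plot rectangle, so a handful of satellite distances
at the boundary are shorter than drawn.
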