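---
title: "Methods: the feeding-niche-partitioning pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the feeding-niche-partitioning pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeniche)
```

This vignette is the package's own account of its methods: what is
computed, which conventions were fixed where several were defensible, and
what the synthetic-data checks do and do not demonstrate.

## The trait space

Six functional traits related to resource use define the niche space:
intertegular distance (ITD, cm; a body-size proxy that scales with foraging
range), relative tongue length (cm; flower-depth access), feeding
specialization (lecty), phenology start and end (weeks from the start of
the year), and daytime activity (hours/day). ITD, tongue length and
daytime activity are measured on each individual; lecty and the phenology
weeks are species-level values joined onto individuals, so conspecifics
share them. Units are kept exactly as recorded; z-scoring (below) makes
them immaterial to distances.

Three conventions are fixed here:

* **Lecty encoding.** Oligolectic = 1, polylectic = 0, then z-scored like
  the continuous axes. This keeps a single Euclidean geometry over all six
  axes, which the mean-pairwise-distance statistic requires. The cost is
  that a binary axis contributes a two-point marginal; its scaled
  magnitude depends on the oligolectic share, which is the standard
  behavior of mixing binary traits into Gower-free Euclidean spaces.
* **Scaling pool.** Axes are centered and scaled *globally*, over all
  retained individuals pooled across sites and groups — not per site —
  because per-site FNP values are subsequently compared across sites in
  one model; per-site scalers would give each site its own unit. The
  sample standard deviation (n − 1) is used, matching the default of
  mainstream statistical environments.
* **Missing data.** Complete cases only. An individual missing any
  individual-level measurement, or whose species lacks a complete
  species-level trait row, is dropped and logged with its reason; the
  exclusion log plus the retained rows always account exactly for the
  input. No imputation: the exclusions in the motivating data are few and
  non-random (damaged specimens, species missing from trait databases),
  and imputing them would manufacture trait positions for exactly the
  individuals whose position is unknown.

Degenerate inputs fail loudly: a zero-variance axis is an error naming the
axis (it cannot be z-scored and would contribute nothing to distances), as
is an empty complete-case set.

## Feeding niche partitioning

For a site with `n` wild and `m` honeybee individuals, FNP is the
arithmetic mean of all `n * m` between-group Euclidean distances on the six
scaled axes. Within-group pairs are excluded by construction — the statistic
measures separation *between* the community and the honeybee population,
not diversity within either. Properties that the tests verify: exact
agreement with a double-loop oracle; invariance to row order, to honeybee
replication, and to common orthogonal transforms; monotonicity under radial
expansion of the wild cloud about the honeybee centroid. A site lacking
either group gets `NA`, never 0: zero would assert perfect overlap.

No ordination or dimensionality reduction is applied; every axis enters
with weight 1. Two transparent decompositions report per-trait influence,
since the influence computation behind the original appendix figure is not
specified in print: the leave-one-axis-out change in FNP, and the
single-axis FNP (mean absolute between-group difference on that axis
alone). For any single pair the six single-axis distances obey the
Pythagorean identity with the full distance, which the tests exploit as an
oracle. Species-level dissimilarity to honeybees pools each wild species'
individuals across sites — one ordering for a study — with a per-site
variant behind the `site` argument.

## Landscape predictors

Green and impervious fractions use a **cell-center membership rule**: the
fraction of grid cells of the class group among all cells whose centers lie
within the radius (boundary inclusive). The alternative — area-weighted
polygon intersection — differs by at most one cell ring and is not
oracle-checkable by enumeration; the cell-center rule is deterministic and
exactly testable against brute force, which the acceptance checks do on
100 × 100 grids. Hive counts sum register points within the radius,
boundary inclusive (the convention had to be fixed; inclusive keeps
`hive_count` monotone in radius with no ambiguity at exact distances).
Geometry is planar Euclidean in a projected metric CRS: at city extents
(~10 km) geodesic corrections are far below one cell.

## The piecewise SEM engine

Each endogenous variable is the response of one OLS sub-model with
intercept; all responses are modeled Gaussian, including counts — the
composite-linear-model convention — so no GLM family choices enter.

* **Offsets.** A declared offset enters the response with coefficient
  fixed at 1: the model is fitted to response minus offset, and R² is
  reported on that adjusted response. Whether sampling effort should enter
  the motivating analysis as a raw-hours or log offset is not stated in
  print, so the default model declares no offset and the machinery is
  exposed via `offset()` terms in `sem_model()` formulas; the generator
  records per-site effort (27/36/45 h with weights 8/11/4, the study's
  3-/4-/5-day schedule at 9 h/day) so either choice can be exercised.
* **Standardization.** `b_std = b_raw * sd(x) / sd(y)` with sample sds over
  sites; `sd(y)` is taken on the offset-adjusted response when an offset is
  declared, because that is the modeled quantity. Standardized
  coefficients are invariant to affine unit changes of either variable
  (tested with random rescalings).
* **Basis set.** Shipley's construction: one claim per non-adjacent pair
  conditional on the union of both members' parents, *omitting pairs in
  which both members are exogenous* — their covariance is unconstrained by
  the model, so no independence is implied. For the default
  four-sub-model DAG this yields 10 claims (df = 20). The claim is
  oriented so the tested response is the member that is not an ancestor of
  the other; when neither is, the topologically later node is the
  response, with declaration order as the deterministic tie-break.
* **Fisher's C.** `C = -2 * sum(log(p))`, chi-square with `2k` df; an empty
  basis set gives C = 0 and model p = 1. A claim p of exactly 0 is an
  error rather than silently flooring: it signals an underflowed test
  whose claim should be inspected, and any floor would be an arbitrary
  constant inside a goodness-of-fit statistic.
* **Information criteria.** The C-based piecewise convention:
  `AIC = C + 2K`, `AICc = C + 2K n/(n − K − 1)`, `BIC = C + K log n`, with
  `K` the total number of estimated parameters across sub-models — slopes,
  intercepts and one error variance each. Published piecewise-SEM AICc
  values computed by other conventions (for example sums of per-sub-model
  likelihood AICc, which are scale-dependent) are not comparable across
  conventions; the convention used here is therefore stated in the output.
* **Collinearity screen.** Pairwise Pearson correlations among candidate
  covariates; a pair must exceed |r| = 0.7 *strictly* for its
  lower-priority member to drop (|r| = 0.7 exactly is retained). Priority
  is an explicit user-ordered list, defaulting to the model's predictor
  order, because the choice of which member to keep is scientific, not
  statistical. Correlations are not re-estimated after drops; the screen
  is a report on the original matrix.
* **Moran's I.** Inverse-Euclidean-distance weights, zero self-weight,
  row-standardized by default (configurable, and recorded in the output).
  The analytic p-value uses the normal approximation with the
  randomization-assumption variance — the quantity a permutation test
  targets, and the convention of the standard reference implementations —
  plus an optional Monte-Carlo permutation p. The alternating-ring case
  (I = −1 exactly) and exact agreement of observed/expected/sd/p with an
  independent implementation are both under test.

## The synthetic-study generator

The generator's defaults emulate the motivating study's conditions: 23
garden sites in a 10 km square; a 63-species wild pool whose species-mean
distributions match the printed trait summaries (ITD 1.49 ± 0.87 cm,
relative tongue length 1.37 ± 0.53 cm, phenology start 7.17 ± 2.46 and end
19.14 ± 2.66 weeks, 8 of 63 species oligolectic); roughly 141 wild and 25
honeybee individuals per site; ~1% damaged specimens with one missing
measurement; a hive register of ~540 hives; and a species complex folded
through the alias map. Daytime activity is not printed numerically
(appendix-only), so 6 ± 1.5 h/day was chosen once for the wild pool as a
plausible solitary-bee flight window. The honeybee centroid (ITD 3.1 cm on
the data's scale, tongue 1.9, polylectic, active weeks 10–44, 9 h/day) was
likewise fixed once from general knowledge of *Apis mellifera*: a large,
supergeneralist, long-season, all-day forager. Its long flight season and
generalism are what place it far from the wild cloud in trait space —
which is also why phenology and lecty dominate the trait contributions in
simulated studies.

**Assembly scenarios.** With `d_s` a species' distance to the honeybee
centroid in the z-scored species-mean space, removal probability is
`exp(-d_s^2 / tau^2) * sigma(i)` under competition,
`(1 - exp(-d_s^2 / tau^2)) * sigma(i)` under environmental filtering, and 0
under neutrality, with `sigma(i) = 1 - exp(-i)` a saturating map of
intensity to [0, 1]. The kernel shape is an implementation choice (the
hypotheses are conceptual); Gaussian-in-squared-distance is the smoothest
kernel with a single scale. `tau` defaults to the *median pool distance to
the honeybee centroid*: a fixed constant cannot suit a space whose scale
depends on the pool, whereas the median places the kernel's half-range
inside the occupied region, so competition and environmental filtering
both discriminate among real pool members. Surviving species receive
log-series abundances (`x = 0.96`, mean ≈ 7 individuals per species per
site), the classic sampled-community abundance distribution.

**Two generators, two purposes.** `simulate_site_covariates()` draws
site-level data *directly* from the linear-Gaussian structural model with
independent standard-normal exogenous variables and residual variances set
to one minus the explained variance, so the configured betas are exactly
the ground-truth standardized paths — this is the parameter-recovery and
calibration instrument. `simulate_study()` builds a full study instead:
green fractions come from an actual random land-cover field, hive counts
from actual points, and FNP is *never written* — richer sites draw further
down the similar-to-dissimilar species ranking, so the FNP–richness path
emerges from community composition, the mechanism itself. Consequently the
landscape-derived drivers are spatially correlated and refitted paths
track, rather than equal, the configured values; recovery to ±0.05 is
asserted only for the covariate simulator.

The generator does **not** emulate: foraging behavior or movement,
within-season phenology dynamics, detection/sampling biases beyond the
effort column, pathogen exchange, or real land-cover spatial structure.
Passing tests therefore demonstrate the correctness and calibration of the
estimators under the stated model, not the field conclusions themselves.

## Numerical choices and problem sizes

Distances use the Gram-matrix identity with a clamp at zero before the
square root (floating-point cancellation can produce tiny negatives).
Oracle agreement is asserted to 1e-10; scaler round-trips to 1e-9; OLS
against the normal equations to 1e-8. Ties in trait-contribution ranking
break by axis order; ties in species dissimilarity keep first-appearance
order (stable sort). The test suite uses 100 random FNP fixtures of up to
20 individuals; 10 intensity levels × 50 replicate sites per scenario;
2000 replicates at n = 100 for d-separation calibration; n = 2000 sites
(and 200 replicates for coverage) for SEM recovery; 10 000 permutations at
n = 23 for Moran agreement; and 100 × 100 grids / 1000 hive points for the
landscape oracles — sizes at which the Monte-Carlo error of each check is
comfortably below its assertion band.

## Known limitations

* All sub-models are Gaussian; count responses are not given GLM families,
  by design fidelity rather than statistical preference.
* The trait space is unweighted Euclidean; a binary axis's contribution is
  tied to its prevalence, and no trait covariance structure is modeled.
* The d-separation engine handles offsets but not random effects; the
  site-level composition of linear models is the supported design.
* `AICc` comparability across software depends on the parameter-count
  convention, as discussed above.
* The benchmark entry point (`envidat_benchmark()`) requires the user to
  obtain and reshape the deposited field data; the package ships only
  synthetic stand-ins, clearly labeled as such.
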