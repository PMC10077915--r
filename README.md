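# beeniche

Quantifying feeding niche partitioning between wild bees and honeybees, and
testing what drives it.

Urban beekeeping adds large numbers of managed honeybees (*Apis mellifera*)
to landscapes that also support diverse wild-bee communities, raising the
question of whether the two compete for floral resources. `beeniche`
implements a trait-based answer for site-level capture data: it measures how
far a site's wild-bee community sits from its honeybee population in a
multidimensional feeding-trait space, and links that distance to resource
availability and beekeeping intensity at local and landscape scales with a
piecewise structural equation model (SEM).

The package is aimed at community ecologists working with individual-level
trait data on pollinators (or any taxon with a focal "dominant" population),
and at anyone who wants a fully testable, simulation-backed implementation
of the between-group mean-pairwise-distance statistic and of piecewise SEM
machinery (d-separation, Fisher's C, information criteria, Moran's I).

## The statistic and the model

**Feeding niche partitioning (FNP).** Each captured individual is a point in
a six-axis trait space: intertegular distance (ITD), relative tongue length,
feeding specialization (lecty, coded oligolectic = 1 / polylectic = 0),
phenology start and end (weeks), and daytime activity (h/day). Three axes
are measured on every individual, three are species-level values joined from
a trait table; every axis is z-scored over all retained individuals. For a
site with wild individuals *w*<sub>1..n</sub> and honeybee individuals
*h*<sub>1..m</sub>,

    FNP = (1 / nm) * sum_i sum_j || w_i - h_j ||

the mean Euclidean distance over all between-group pairs; within-group pairs
are excluded. FNP = 0 means complete niche overlap; large FNP means the
wild community is functionally far from the honeybees. Because individuals,
not species means, are the points, intraspecific trait variation enters the
metric directly.

**The SEM.** Site-level FNP, wild-bee species richness, plant species
richness and honeybee abundance are each the response of one OLS sub-model
over a shared causal DAG (richness and abundance predictors at 100/500 m
buffer scales, management intensity, hive counts). Missing paths are tested
by Shipley's d-separation: every non-adjacent variable pair (with at least
one endogenous member) yields an independence claim tested by regression,
and the claim p-values combine into Fisher's C = -2 Σ ln p, chi-square with
2k df, plus AICc/BIC on the C-based convention. Moran's I (inverse-distance
weights) screens responses and residuals for spatial autocorrelation.

A synthetic-study generator reproduces the study design (23 garden sites, a
63-species wild pool, honeybees with small trait variance) and implements
the competing community-assembly hypotheses as radial kernels in trait
space — competition removes honeybee-*similar* species, environmental
filtering removes honeybee-*dissimilar* species — so every pipeline stage
can be verified against known ground truth.

## Worked example

Simulate a full 23-site study, write it to disk, and run the complete
pipeline (traits → FNP → landscape predictors → collinearity screen → SEM):

```r
library(beeniche)

cfg   <- simulation_config(seed = 2026)
study <- simulate_study(cfg)
dir   <- file.path(tempdir(), "demo"); write_study(study, dir)
res   <- run_all(run_config(dir, file.path(tempdir(), "demo_out"), seed = 2026))

head(res$fnp, 5)
#> # A tibble: 5 × 5
#>   site_id   fnp n_wild n_honeybee n_pairs
#> 1 site01   4.10     76         32    2432
#> 2 site02   4.31    166         34    5644
#> 3 site03   4.19    279         22    6138
#> 4 site04   4.20    113         22    2486
#> 5 site05   3.67    102         13    1326

res$fit
#> <sem_fit> 4 sub-models over 23 sites
#>   Fisher's C = 14.28, df = 20, p = 0.816 | AICc = 474.28, BIC = 76.99 (K = 20)
#>   fnp (R2 = 0.66)
#>     wild_richness             0.713 ± 0.164 **
#>     plant_richness           -0.080 ± 0.167
#>     honeybees                 0.361 ± 0.189
#>     ...
```

Reading the output: each site's `fnp` is the mean between-group distance in
scaled-trait units (≈ 4.2 here: the wild community is several pooled
standard deviations from the honeybees). The model p of 0.816 says the
d-separation test found no evidence of missing paths, and the significant
standardized coefficient on `wild_richness` (0.713) reproduces, by
construction of the generator, the mechanism in which richer sites gain
species that are functionally dissimilar to honeybees, raising FNP. Species
can be ranked by their distance to the honeybees with
`species_dissimilarity(res$trait_matrix)`, and per-axis influence with
`trait_contribution(res$trait_matrix)`.

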