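# fasdiet

Quantitative fatty acid signature analysis (QFASA) in R: estimate the diet
composition of a predator from the fatty acid signature of its adipose
tissue, check the estimates with simulation diagnostics, and test how diets
vary with demography, time and environmental covariates using
distance-based permutation statistics.

## Who this is for

Ecologists working with fatty acid signatures — compositional vectors of
individual fatty acids expressed as mass percent of total FAME — who need
the full inference chain that a predator-diet study runs: a multi-species
prey library, calibration-coefficient correction for predator metabolism,
simplex-constrained mixture estimation, prey-on-prey and pseudo-predator
adequacy simulations, permutational MANOVA on the resulting diet
compositions, and back-of-envelope energetics. The package was built around
a polar bear / Arctic prey use case (ringed seal, bearded seal, beluga,
bowhead, seabird), but nothing in it is species-specific. A seeded
synthetic-data generator emulates the whole study design so every stage is
testable without access to archived field data.

## The model

A predator signature is first mapped into prey space with calibration
coefficients (CCs): each component is divided by its CC and the vector is
re-closed. Diet is then the simplex vector α minimizing the symmetrized
Kullback–Leibler distance

d(y, ŷ(α)) = Σᵢ (yᵢ − ŷᵢ) log(yᵢ / ŷᵢ),  ŷ(α) = Σₖ αₖ μₖ,

where μₖ is the mean signature of prey species k. α lives in fatty-acid
(lipid) space; biomass diet proportions use each species' lipid fraction
fₖ (the proportion of consumed prey mass that is lipid):

πₖ = (αₖ / fₖ) / Σⱼ (αⱼ / fⱼ).

Optimization is multi-start (near-vertex, barycenter and seeded random
starts) over a softmax parameterization, verified against an exhaustive
grid-search oracle. Group comparisons use a perMANOVA on chi-square
distances between diet compositions, with sequential sums of squares,
free permutation of observation labels, add-one p-values, and Holm
adjustment across prey-specific tests.

## Worked example

```r
library(fasdiet)

sc  <- synthetic_scenario(seed = 42, n_predators = 30)
lib <- gen_prey_library(sc)
cc  <- gen_calibration(sc$fa, spread = sc$cc_spread, seed = 42)
coh <- gen_predator_cohort(sc, lib, cc)

diet <- batch_estimate(coh$predators, lib, cc = cc, seed = 1)
print(diet)
#> Diet estimates for 30 predators
#>   ringed_seal     41.3 ± 1.9%
#>   bearded_seal    18.9 ± 1.7%
#>   beluga           2.3 ± 0.6%
#>   bowhead         20.4 ± 1.6%
#>   seabird         17.1 ± 1.7%
```

Per-species mean ± SE biomass proportions across the cohort. Does the
model recover a known diet? Build pseudo-predators from a stated truth:

```r
sim <- pseudo_predator(c(ringed_seal = 0.45, bearded_seal = 0.20,
                         beluga = 0.05, bowhead = 0.15, seabird = 0.15),
                       lib, cc = cc, n_runs = 100, seed = 1)
print(sim)
#> Pseudo-predator simulation (100 runs):
#>   ringed_seal    true  45.0%  recovered  45.0 ± 2.5%
#>   bearded_seal   true  20.0%  recovered  19.9 ± 0.9%
#>   beluga         true   5.0%  recovered   5.0 ± 1.0%
#>   bowhead        true  15.0%  recovered  15.0 ± 1.0%
#>   seabird        true  15.0%  recovered  15.1 ± 4.7%
```

Which prey proportions differ among sex/age classes? One perMANOVA per
prey on the (pₖ, 1 − pₖ) composition, Holm-adjusted:

```r
res <- per_prey_permanova(diet, coh$predators$info, ~ class,
                          n_perm = 999, seed = 1)
#>        species pseudo_F p_raw p_holm
#> 1  ringed_seal    6.976 0.002  0.010
#> 2 bearded_seal    0.602 0.625  1.000
#> 3       beluga    0.377 0.881  1.000
#> 4      bowhead    6.074 0.004  0.016
#> 5      seabird    0.217 0.871  1.000
```

The generator's default adult-male tilt (less ringed seal, more bowhead)
is exactly what the test recovers. Finally, what does a 17% seabird diet
mean in biomass terms for 900 bears needing 12,000 kcal/day?

```r
print(energetics_chain())
#> Energetics chain:
#>   fat_only_intake               1.333  (~1.3 kg fat/bear/day)
#>   protein_only_intake               3  (~3 kg protein/bear/day)
#>   mixed_fat_intake              1.067  (~1.1 kg fat/bear/day)
#>   mixed_protein_intake            0.6  (~0.6 kg protein/bear/day)
#>   population_annual_fat         328.5  (~328 thousand kg fat/yr)
#>   prey_annual_fat               55.85  (~56 thousand kg fat/yr)
#>   prey_biomass_required         558.5  (~558 thousand kg prey/yr)
#>   regional_biomass            1.4e+07  (~1.4e+07 kg)
#>   percent_of_regional           3.989  (~4 %)
```

About 560 thousand kg of seabirds per year — roughly 4% of a 14-million-kg
regional seabird biomass.

## Command line

`inst/cli/fasdiet.R` exposes the pipeline as subcommands
(`estimate`, `prey-on-prey`, `pseudo-predator`, `stats`, `energetics`,
`synth`), e.g.

```sh
Rscript inst/cli/fasdiet.R synth --out-prefix demo --seed 4
Rscript inst/cli/fasdiet.R estimate --predators demo_predators.csv \
    --prey demo_prey.csv --lipids demo_lipids.csv --cc demo_cc.csv \
    --out demo_diet.csv --seed 4
Rscript inst/cli/fasdiet.R stats --diet demo_diet.csv --out demo_stats.csv
```

All tabular I/O is delimited text; result files carry a `#` provenance
header with version, seed and parameters.

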