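# elevsense

Tools for asking, of any multi-band elevational survey of a species-rich
assemblage: **how strongly is composition structured by elevation, and how
does that sensitivity compare across transects?** The motivating design is
light-trapped moth assemblages on forested gradients — three transects in
different bioregions, each with four elevational bands of five plots — but
the machinery applies to any plot × species count matrix with band and
elevation metadata.

## What it computes

Given a `CommunityExperiment` (a `SummarizedExperiment` of integer counts,
species × plots, with `transect` / `band` / `elevation_m` metadata):

1. **Abundance-standardized richness** — analytic (Hurlbert) individual-based
   rarefaction, `E[S] = Σᵢ [1 − C(N−Nᵢ, n)/C(N, n)]`, evaluated exactly in
   log space at a standard depth (canonically n = 364).
2. **'Common' species** — the detection rule `P = 1 − (1 − 1/n)^N`: the
   smallest N giving detection probability ≥ P over n plots (N = 14 for
   n = 5, P = 0.95).
3. **Four similarity indices** — Sørensen and Bray–Curtis on common species,
   Chao's abundance-based Sørensen estimator (`2UV/(U+V)` with
   singleton/doubleton corrections) and the closed-form hypergeometric
   Raup–Crick probability on all species.
4. **PERMANOVA** — one-way pseudo-F from among/within sums of squared
   dissimilarities, p by unrestricted label permutation (default 4999), with
   pairwise post hoc t = √F tests.
5. **Elevation-decay regression** — OLS of pairwise similarity on Δelevation;
   the slope is the sensitivity measure.
6. **Indicator species** — Dufrêne–Legendre IndVal = 100·A·B over all
   contiguous band ranges except the full transect (nine groupings for four
   bands), permutation significance, and a null-model **standardized effect
   size** of the significant-indicator count:
   `ES = (observed − mean(null)) / sd(null)` over datasets with shuffled
   plot-to-band assignments.

A synthetic generator (`generateAssemblage()`, `generateMultiTransect()`)
produces transects with Gaussian elevational niches, a long-tailed log-normal
abundance distribution and negative-binomial detection, calibrated to the
motivating survey's conditions, so the whole pipeline is testable without
field data.

## Worked example

```r
library(elevsense)

rule <- commonSpeciesThreshold(5, 0.95)
rule
#> CommonSpeciesRule: N >= 14 (detection P >= 0.95 over n = 5 plots)

ce <- generateAssemblage(syntheticConfig(nicheWidthSigma = 150, seed = 7))
ce
#> CommunityExperiment: 1500 species x 20 plots, 10777 individuals
#>   transects: T1
#>   bands: 800 < 1000 < 1200 < 1400

depth <- min(364, min(plotTotals(ce)))          # 330 for this realization
head(rarefiedRichness(ce, depth), 3)
#>     plot_id n_standard expected_species observed_species plot_total
#> 1 T1_800_p1        330         88.11945              124        586
#> 2 T1_800_p2        330         84.32633              122        638
#> 3 T1_800_p3        330         94.42639              130        602

common <- filterCommonSpecies(ce, rule)         # 129 of 1500 species
sim <- pairwiseSimilarity(ce, "sorensen", rule = rule)

permanova(asDissimilarity(sim), SummarizedExperiment::colData(ce)$band,
          nPermutations = 4999, seed = 1)
#> PERMANOVA: pseudo-F = 17.04 (df = 3, 16), p = 0.0002 (4999 permutations)

distanceDecayFit(sim, ce)
#> Distance decay (sorensen): slope = -0.00109 per m, intercept = 0.744,
#>   R^2 = 0.889 (190 pairs)

res <- indicatorSignificance(common, nPermutations = 999, seed = 2)
countSignificant(res)$total
#> [1] 83

effectSizeNullModel(common, nNull = 99, nPermutations = 999,
                    innerPermutations = 199, seed = 3)
#> Indicator effect size: observed = 84 significant species,
#>   null = 4.78 +/- 5.88 over 99 datasets, ES = 13.483
```

Reading the numbers: assemblage composition differs strongly among bands
(pseudo-F = 17, p at the permutation floor); similarity falls by about 0.11
per 100 m of elevational separation with a tight linear fit (R² = 0.89); and
the 83–84 significant indicator species (the two runs use independent
permutation streams, so the Monte-Carlo counts differ by one) are ~13
standard deviations above what shuffled plot assignments produce — a
strongly elevationally structured fauna, as expected for a 150 m niche
width. `runPipeline()` chains all stages over every transect and writes
CSV/JSON artefacts plus a summary ranking transects by decay slope and
effect size.

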