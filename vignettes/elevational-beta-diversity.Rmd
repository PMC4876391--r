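---
title: "Quantifying elevational sensitivity of species assemblages"
author: "elevsense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying elevational sensitivity of species assemblages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elevsense)
```

# The question and the data model

Assemblages of highly diverse, mobile taxa — light-trapped moths are the
motivating case — change composition along elevational gradients, and the
*rate* of that change is a measure of how sensitive the fauna is to the
climatic differences that elevation encodes. `elevsense` quantifies that
sensitivity for a standard survey design: one or more elevational transects,
each with a small number of elevational bands (replicate plots per band),
and a plot-by-species matrix of integer counts.

The central container is `CommunityExperiment`, a `SummarizedExperiment`
with species as rows, plots as columns, a `"counts"` assay, and the plot
metadata (`transect`, `band`, `elevation_m`, optional `stratum`/`site`) in
`colData`. Vertically stratified samples (canopy vs understorey) are summed
per plot with `poolStrata()` before analysis, because many species are shared
between strata within a plot.

# Standardizing richness

Catch sizes differ enormously between plots, and observed richness is
strongly correlated with abundance. `rarefiedRichness()` therefore reports
the Hurlbert expectation

$$E[S] \;=\; \sum_i \left[ 1 - \binom{N-N_i}{n} \middle/ \binom{N}{n} \right]$$

the expected species count in a random subsample of $n$ individuals from a
plot with total $N$ and species abundances $N_i$. The binomial ratios are
evaluated exactly in log space (`lchoose`), so there is no Monte-Carlo noise:
this is the analytic expectation of an abundance-based accumulation curve,
read off at a standard depth. The canonical depth is $n = 364$, the smallest
plot total of the motivating survey; the pipeline caps the requested depth at
the smallest plot total of each transect.

# 'Common' species

Incidence-based indices are dominated by sampling noise when most species
are singletons. Following the detection argument of Novotný and colleagues:
if a habitat contributes $n$ equally likely plots and a species has $N$
individuals there, the chance of seeing it in a given plot (assuming no
within-habitat beta diversity) is $P = 1 - (1 - 1/n)^N$.
`commonSpeciesThreshold(n, P)` returns the smallest integer $N$ meeting a
target $P$; for $n = 5$ and $P = 0.95$ the threshold is 14 individuals, and
the comparison is inclusive (a species with exactly 14 individuals is
common). Commonness is assessed within each transect separately, which
treats the transect as the "habitat" of the detection model.

# Four complementary similarity indices

`pairwiseSimilarity()` builds a labelled symmetric matrix for one index over
all within-transect plot pairs (mixing transects is refused: species pools
are effectively disjoint between transects, so cross-transect similarities
are near zero and meaningless for gradient questions). The four indices
answer deliberately different questions:

* **Sørensen** ($2a/(2a+b+c)$, presence/absence, common species only):
  compositional turnover among reliably detected species.
* **Bray–Curtis** (on proportional abundances of common species relative to
  each plot's *all-species* total): turnover weighted by abundance structure.
* **Chao–Sørensen estimated** (all species): corrects shared-species
  proportions $U, V$ for unseen shared species using shared singletons and
  doubletons, then combines them as $2UV/(U+V)$. When no shared species is a
  singleton or doubleton in the other sample the correction vanishes and the
  index reduces to the classic abundance-based Sørensen. Conventions: when
  $f^{+}_2 = 0$ the divisor uses $\max(f^{+}_2, 1)$, and $U, V$ are capped
  at 1.
* **Raup–Crick** (all species): the probability that two random plots of the
  same richnesses, drawn from the transect species pool with equal weights,
  would share *fewer* species than observed — $P(J < j_{obs})$ with $J$
  hypergeometric. It is computed in closed form, which is deterministic and
  matches the verbal definition of drawing plots "at random from the species
  pool". A Monte-Carlo variant weighting species by occurrence frequency is
  available (`method = "simulation"`) for sensitivity analysis; the two can
  differ when occupancy is very uneven, and the closed form is the default.
  The Raup–Crick diagonal is stored as `NA`: self-similarity is not a
  probability of interest.

`asDissimilarity()` converts any of these to $d = 1-s$ for downstream tests;
converting Raup–Crick warns, because a probability is not a metric distance
(the warning mirrors how such matrices are nonetheless used in practice).

# Stratification: PERMANOVA

`permanova()` implements the one-way permutational MANOVA directly on the
dissimilarity matrix:

$$SS_T = \tfrac{1}{N}\textstyle\sum_{i<j} d_{ij}^2,\qquad
  SS_W = \sum_g \tfrac{1}{n_g} \sum_{i<j \in g} d_{ij}^2,\qquad
  F = \frac{(SS_T - SS_W)/(g-1)}{SS_W/(N-g)}$$

with $p$ from unrestricted permutation of plot labels, the observed labelling
counted once (so $p \ge 1/(n_{perm}+1)$; the default is 4999 permutations).
For a one-way design, Type III and sequential sums of squares coincide.
`pairwisePermanova()` reports $t = \sqrt{F}$ per band pair with its own
permutation $p$; raw p-values are primary (the protocol applies no
multiplicity correction) and a Bonferroni column is appended for users who
want one.

# The elevation-decay regression

`distanceDecayFit()` regresses pairwise similarity on the absolute
difference in plot elevation by ordinary least squares, treating the
$\binom{P}{2}$ plot pairs as independent observations — the conventional
descriptive fit for decay plots. A steeper negative slope means a fauna more
sensitive to elevation. Conventions: constant similarity returns slope 0 and
$R^2 = 0$; fewer than three distinct elevational separations is an error;
Raup–Crick input is refused unless forced, since a logistic, not linear,
trend is expected of a probability. Pairs are not independent in truth, so
the default fit is purely descriptive — the slope is what the
between-transect sensitivity comparison needs; a Mantel-style permutation p
(shuffling plot identities, comparing absolute slopes) is available behind
`nPermutations > 0` for users who want inference on a single slope.

# Indicator species and the null-model effect size

`candidateGroupings()` enumerates every contiguous run of bands except the
full transect — for four bands: four singles, three adjacent pairs, two
triples, i.e. nine groupings per species. For a grouping $G$,
`indicatorValue()` computes the Dufrêne–Legendre statistic against the
binary partition {inside $G$, outside $G$}:

$$A = \frac{\bar{x}_{in}}{\bar{x}_{in} + \bar{x}_{out}},\qquad
  B = \frac{\text{occupied plots in } G}{\text{plots in } G},\qquad
  IndVal = 100\,A\,B$$

This binary-partition extension reduces exactly to the original two-group
IndVal and is scale-free per species. A species is deemed indicative of the
grouping where its IndVal peaks (`bestIndicator()`); ties break
deterministically towards fewer bands, then lower elevation.
`indicatorSignificance()` permutes the plot-to-band assignment (band sizes
preserved; 999 permutations by default) and compares each species' maximum
IndVal against its permutation distribution, counting the observed
arrangement once.

Significant-indicator counts cannot be compared across transects with very
different pool sizes, so `effectSizeNullModel()` standardizes them: the full
significance protocol is re-run on `nNull` datasets whose plot-to-band
assignment has been shuffled, and

$$ES = \frac{\text{observed count} - \overline{\text{null counts}}}{sd(\text{null counts})}$$

Each null replicate derives its own seed from the master seed
(counter-based), so runs are reproducible and replicates independent. The
inner significance test inside null datasets defaults to 199 permutations
against 999 for the observed data; the effect size is robust to the inner
count, and the package's own test suite uses a reduced 99 × 99 design to
keep runtimes modest. When the null counts have zero spread the effect size
is flagged undefined rather than reported as infinite. Significance level
$\alpha = 0.05$ is the protocol default and is configurable; no
multiple-testing correction is applied across species (a BH q-value column
is emitted for reference).

Two open choices were resolved as follows: null datasets are unrestricted
shuffles of the plot-to-band assignment (band sizes preserved), and p-values
are recomputed from scratch inside every null dataset rather than reusing
the observed permutation distribution.

# The synthetic community generator

Because the motivating moth counts are not deposited, `generateAssemblage()`
provides data with the statistical structure the analysis assumes:

* **Gaussian elevational niches**: expected count of species $s$ at plot $p$
  is $\mu_{sp} = peak_s \exp(-(e_p - o_s)^2 / 2\sigma^2)$. Gaussian response
  curves are the simplest model producing gradual distance decay; skewed
  niches are out of scope.
* **Niche optima** uniform over the gradient extended by
  `nicheCenterSpread` (default 200 m) beyond both ends, so edge bands are
  not artificially depauperate.
* **Long-tailed SAD**: peak abundances log-normal. The defaults
  (`sadMeanlog = -2.25`, `sadSdlog = 2`, 1500–2000 species) were chosen so
  that a generated transect reproduces the field conditions of the
  motivating survey: 70–90% of species with fewer than 10 individuals,
  roughly 12–20k individuals per transect, smallest plot totals above the
  364-individual rarefaction depth, and 10–20% of recorded species passing
  the commonness threshold.
* **Detection**: negative binomial with $k = 1$ by default (light-trap
  catches are overdispersed); Poisson available for variance-limit checks.
* **Design**: four bands 200 m apart, five plots per band, plot elevations
  jittered ±20 m so analyses can use actual plot elevations rather than band
  labels. `generateMultiTransect()` combines transects with disjoint species
  namespaces, emulating faunas that share essentially no species between
  bioregions.

The generator stores its truth (optima, widths, peaks, plot elevations) for
parameter-recovery tests: narrower niches must steepen the Sørensen decay
slope and inflate the indicator effect size, and shuffling away the
structure must drive the effect size to mean ≈ 0. What the generator does
*not* emulate — spatial autocorrelation within bands, phenology, taxonomic
error, canopy/ground stratification — bounds what passing tests show about
field data: they validate the statistical machinery and its directional
behaviour, not any claim about real moths.

# Numerical choices and degenerate inputs

* Rarefaction uses `lchoose`; a species with $N - N_i < n$ contributes
  exactly 1.
* Empty presence sets or all-zero abundance vectors yield similarity 0 with
  a warning rather than `NaN`.
* Permutation exceedance comparisons use a $10^{-9}$–$10^{-10}$ tolerance so
  that ties (e.g. duplicated plots) count as exceedances, keeping p-values
  conservative.
* Band labels are strings, ordered by mean `elevation_m`, never
  lexicographically (so "900" sorts before "1100").
* The problem sizes used in the package's own checks — 1500–2000 species per
  synthetic transect, 10–12 seeds per Monte-Carlo claim, a 99 × 99 nested
  permutation design for effect sizes, 4999-permutation PERMANOVAs — were
  chosen as the smallest designs that make the directional claims
  statistically stable.

# Limitations

* Only one-way PERMANOVA designs; no nested or multi-factor models.
* The decay fit is descriptive OLS over non-independent pairs.
* No turnover/nestedness partitions of beta diversity; no occurrence-only
  input (binarization happens inside the Sørensen/Raup–Crick paths).
* The linear mixed-effects model of rarefied richness against elevation is
  deliberately not reimplemented: `rarefiedRichness()` emits a tidy table
  any mixed-model package consumes directly.
* NMDS ordination is a visualization hook (`plotOrdination()`, delegating to
  `vegan::metaMDS`); stress minimization is not part of this package.
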