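Package: elevsense
Title: Elevational Sensitivity of Species Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how strongly species assemblages are
    structured along elevational gradients. Implements abundance-standardized
    (rarefied) richness, a detection-probability rule for selecting 'common'
    species, four complementary pairwise similarity indices (Sorensen,
    Bray-Curtis, Chao's abundance-based Sorensen estimator and the
    probabilistic Raup-Crick index), one-way PERMANOVA with pairwise post hoc
    tests, distance-decay regression of similarity on elevational separation,
    and a Dufrene-Legendre indicator-value protocol over contiguous elevational
    band ranges whose significant-indicator count is compared against a
    shuffled-sample null model via a standardized effect size. A synthetic
    community generator with Gaussian elevational niches and long-tailed
    abundance distributions emulates multi-transect light-trapping designs so
    the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
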