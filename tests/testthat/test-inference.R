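toyDist <- function(within = 0.2, between = 1.0) {
    d <- matrix(between, 4, 4,
                dimnames = list(paste0("p", 1:4), paste0("p", 1:4)))
    d[1, 2] <- d[2, 1] <- within
    d[3, 4] <- d[4, 3] <- within
    diag(d) <- 0
    d
}

test_that("pseudo-F matches hand-derived sums of squares", {
    r <- permanova(toyDist(), c("a", "a", "b", "b"), nPermutations = 99,
                   seed = 1)
    # SS_T = 4.08/4 = 1.02, SS_W = 0.04, SS_A = 0.98, F = 0.98 / (0.04/2)
    expect_equal(r@ssTotal, 1.02)
    expect_equal(r@ssWithin, 0.04)
    expect_equal(r@ssAmong, 0.98)
    expect_equal(pseudoF(r), 49)
    expect_identical(r@dfAmong, 1L)
    expect_identical(r@dfWithin, 2L)
    # all pairwise distances equal -> F = 1
    req <- permanova(toyDist(1, 1), c("a", "a", "b", "b"),
                     nPermutations = 99, seed = 1)
    expect_equal(pseudoF(req), 1)
    expect_equal(pValue(req), 1)
})

test_that("sums of squares decompose and match vegan::adonis2", {
    skip_if_not_installed("vegan")
    set.seed(31)
    for (rep in 1:5) {
        pts <- matrix(rnorm(24), 12, 2)
        d <- as.matrix(dist(pts))
        dimnames(d) <- list(paste0("p", 1:12), paste0("p", 1:12))
        g <- rep(c("a", "b", "c"), each = 4)
        r <- permanova(d, g, nPermutations = 19, seed = rep)
        expect_equal(r@ssAmong + r@ssWithin, r@ssTotal, tolerance = 1e-9)
        a <- vegan::adonis2(as.dist(d) ~ g, permutations = 19)
        expect_equal(pseudoF(r), a$F[1], tolerance = 1e-10)
        expect_equal(r@ssAmong, a$SumOfSqs[1], tolerance = 1e-10)
        expect_equal(r@ssWithin, a$SumOfSqs[2], tolerance = 1e-10)
    }
})

test_that("pseudo-F is invariant under relabelling of plots", {
    set.seed(7)
    d <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
    dimnames(d) <- list(paste0("p", 1:10), paste0("p", 1:10))
    g <- rep(c("a", "b"), each = 5)
    f0 <- pseudoF(permanova(d, g, nPermutations = 9, seed = 1))
    perm <- sample(10)
    f1 <- pseudoF(permanova(d[perm, perm], g[perm], nPermutations = 9,
                            seed = 1))
    expect_equal(f0, f1, tolerance = 1e-12)
})

test_that("permutation p respects its floor and uniformity under the null", {
    set.seed(3)
    d <- as.matrix(dist(matrix(rnorm(16), 8, 2)))
    dimnames(d) <- list(paste0("p", 1:8), paste0("p", 1:8))
    r <- permanova(d, rep(c("a", "b"), each = 4), nPermutations = 49, seed = 2)
    expect_gte(pValue(r), 1 / 50)

    # structureless data: p approximately uniform on the permutation grid
    set.seed(99)
    ps <- replicate(150, {
        dd <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
        dimnames(dd) <- list(paste0("p", 1:10), paste0("p", 1:10))
        pValue(permanova(dd, sample(rep(c("a", "b"), each = 5)),
                         nPermutations = 99))
    })
    # ties are expected on the discrete permutation grid
    expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("group-size and symmetry preconditions are enforced", {
    d <- toyDist()
    expect_error(permanova(d, c("a", "a", "a", "b"), 99), "at least 2 plots")
    expect_error(permanova(d, c("a", "a", "a", "a"), 99), "two groups")
    bad <- d; bad[1, 2] <- 0.9
    expect_error(permanova(bad, c("a", "a", "b", "b"), 99), "symmetric")
})

test_that("pairwise tests report t = sqrt(F) per band pair", {
    set.seed(12)
    ce <- generateAssemblage(syntheticConfig(nSpecies = 400,
                                             nicheWidthSigma = 100,
                                             seed = 12))
    rule <- commonSpeciesThreshold(5, 0.95)
    d <- asDissimilarity(pairwiseSimilarity(ce, "sorensen", rule = rule))
    band <- SummarizedExperiment::colData(ce)$band
    pw <- pairwisePermanova(d, band, nPermutations = 99, seed = 5)
    expect_equal(nrow(pw), 6L)
    D <- as.matrix(d)
    for (k in seq_len(nrow(pw))) {
        idx <- band %in% c(pw$group1[k], pw$group2[k])
        rk <- permanova(D[idx, idx], band[idx], nPermutations = 9, seed = 1)
        expect_equal(pw$t[k], sqrt(pseudoF(rk)), tolerance = 1e-12)
    }
    expect_equal(pw$p_bonferroni, pmin(1, pw$p_value * 6))
})

test_that("duplicated bands give minimal t and p near 1", {
    m <- matrix(rpois(40, 5), 4, 10)
    m <- rbind(m, m)  # bands "800" and "1000" identical
    ce <- makeCE(m, bands = rep(c("800", "1000"), each = 4))
    sim <- pairwiseSimilarity(ce, "bray_curtis",
                              rule = commonSpeciesThreshold(4, 0.95))
    pw <- pairwisePermanova(asDissimilarity(sim),
                            SummarizedExperiment::colData(ce)$band,
                            nPermutations = 199, seed = 3)
    expect_gt(pw$p_value[1], 0.9)
})

test_that("decay fit recovers exact linear data and the OLS closed form", {
    elev <- c(p1 = 800, p2 = 1000, p3 = 1200, p4 = 1400)
    v <- outer(elev, elev, function(a, b) 0.9 - 5e-4 * abs(a - b))
    diag(v) <- 1
    dimnames(v) <- list(names(elev), names(elev))
    sim <- new("SimilarityMatrix", values = v, indexName = "sorensen",
               speciesScope = "common", transect = "T1")
    fit <- suppressWarnings(distanceDecayFit(sim, elev))  # perfect-fit note
    expect_equal(decaySlope(fit), -5e-4, tolerance = 1e-12)
    expect_equal(fit@intercept, 0.9, tolerance = 1e-12)
    expect_equal(fit@rSquared, 1, tolerance = 1e-9)
    expect_identical(fit@nPairs, 6L)  # C(4, 2) plot pairs

    # random data: slope equals the independent two-pass OLS formula
    set.seed(6)
    v2 <- v
    v2[upper.tri(v2)] <- runif(6)
    v2[lower.tri(v2)] <- t(v2)[lower.tri(v2)]
    sim2 <- new("SimilarityMatrix", values = v2, indexName = "sorensen",
                speciesScope = "common", transect = "T1")
    dEl <- abs(outer(elev, elev, "-"))[upper.tri(v2)]
    expect_equal(decaySlope(distanceDecayFit(sim2, elev)),
                 refOlsSlope(dEl, v2[upper.tri(v2)]), tolerance = 1e-12)
})

test_that("decay conventions: constant similarity, few separations, Raup-Crick", {
    elev <- c(p1 = 800, p2 = 1000, p3 = 1200, p4 = 1400)
    v <- matrix(0.4, 4, 4, dimnames = list(names(elev), names(elev)))
    diag(v) <- 1
    sim <- new("SimilarityMatrix", values = v, indexName = "sorensen",
               speciesScope = "common", transect = "T1")
    fit <- distanceDecayFit(sim, elev)
    expect_equal(decaySlope(fit), 0)
    expect_equal(fit@rSquared, 0)

    two <- c(p1 = 800, p2 = 800, p3 = 1000, p4 = 1000)
    expect_error(distanceDecayFit(sim, two), "distinct")

    rc <- new("SimilarityMatrix",
              values = {vv <- v; diag(vv) <- NA; vv},
              indexName = "raup_crick", speciesScope = "all", transect = "T1")
    expect_error(distanceDecayFit(rc, elev), "non-metric")
    expect_s4_class(distanceDecayFit(rc, elev, force = TRUE), "DecayFit")
})

test_that("the Mantel-style permutation p separates real from shuffled decay", {
    set.seed(44)
    ce <- generateAssemblage(syntheticConfig(nSpecies = 400,
                                             nicheWidthSigma = 100, seed = 44))
    rule <- commonSpeciesThreshold(5, 0.95)
    sim <- pairwiseSimilarity(ce, "sorensen", rule = rule)
    fit <- distanceDecayFit(sim, ce, nPermutations = 199, seed = 9)
    expect_lte(fit@pValue, 0.01)
    expect_gte(fit@pValue, 1 / 200)
    # shuffled elevations: no decay signal, p typically large
    elev <- stats::setNames(
        sample(SummarizedExperiment::colData(ce)$elevation_m),
        plotIDs(ce))
    fit0 <- distanceDecayFit(sim, elev, nPermutations = 199, seed = 10)
    expect_gt(fit0@pValue, 0.05)
    # default fit computes no permutation p
    expect_true(is.na(distanceDecayFit(sim, ce)@pValue))
})

test_that("narrower niches steepen the decay slope on synthetic transects", {
    rule <- commonSpeciesThreshold(5, 0.95)
    slopes <- vapply(c(100, 400), function(sig) {
        ce <- generateAssemblage(syntheticConfig(nSpecies = 600,
                                                 nicheWidthSigma = sig,
                                                 seed = 42))
        decaySlope(distanceDecayFit(
            pairwiseSimilarity(ce, "sorensen", rule = rule), ce))
    }, numeric(1))
    expect_lt(slopes[1], slopes[2])  # more negative for sigma = 100
})
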