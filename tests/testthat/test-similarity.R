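test_that("Sorensen similarity matches its definition", {
    expect_equal(sorensenSimilarity(c("X", "Y"), c("X", "Y")), 1)
    expect_equal(sorensenSimilarity(c("X", "Y"), "X"), 2 / 3)
    expect_equal(sorensenSimilarity("X", "Y"), 0)
    expect_warning(z <- sorensenSimilarity(character(), character()), "empty")
    expect_equal(z, 0)
})

test_that("Bray-Curtis similarity matches hand computation", {
    expect_equal(brayCurtisSimilarity(c(0.3, 0.1), c(0.3, 0.1)), 1)
    expect_equal(brayCurtisSimilarity(c(0.5, 0), c(0, 0.5)), 0)
    expect_equal(brayCurtisSimilarity(c(0.4, 0.2), c(0.2, 0.2)), 0.8)
    expect_error(brayCurtisSimilarity(c(-0.1, 0), c(0, 0)), "non-negative")
    expect_warning(z <- brayCurtisSimilarity(c(0, 0), c(0, 0)), "empty")
    expect_equal(z, 0)
})

test_that("Chao-Sorensen estimator reproduces hand-derived cases", {
    # shared species neither singleton nor doubleton: corrections vanish
    expect_equal(chaoSorensenSimilarity(c(4, 1, 0), c(3, 0, 2)),
                 2 * 0.8 * 0.6 / 1.4)
    expect_equal(chaoSorensenSimilarity(c(4, 1, 0, 0), c(0, 0, 3, 2)), 0)
    # one shared species that is rare in both samples exercises the
    # correction terms: U = 1/5, V = 2/2 + (4/5)(1/2)(2/2) capped at 1
    expect_equal(chaoSorensenSimilarity(c(4, 1), c(0, 2)), 2 * 0.2 / 1.2)
    x <- c(5, 3, 2, 1)
    expect_equal(chaoSorensenSimilarity(x, x), 1)  # identical, capped
})

test_that("Chao-Sorensen reduces to the classic abundance Sorensen without rare shared species", {
    set.seed(3)
    for (rep in 1:10) {
        x <- sample(3:20, 6)  # every count >= 3: no singletons/doubletons
        y <- sample(3:20, 6)
        drop <- sample(6, 2)
        x[drop[1]] <- 0; y[drop[2]] <- 0
        shared <- x > 0 & y > 0
        U <- sum(x[shared]) / sum(x)
        V <- sum(y[shared]) / sum(y)
        expect_equal(chaoSorensenSimilarity(x, y), 2 * U * V / (U + V))
    }
})

test_that("Chao-Sorensen U,V agree with vegan's Chao-Jaccard dissimilarity", {
    skip_if_not_installed("vegan")
    # vegan's "chao" is the Jaccard form 1 - UV/(U+V-UV) of the same U, V.
    # If both routes compute the same U, V, the Sorensen form s = 2UV/(U+V)
    # determines the Jaccard similarity exactly as s/(2-s).
    set.seed(9)
    tested <- 0
    for (rep in 1:40) {
        x <- rpois(12, 1.5); y <- rpois(12, 1.5)  # many shared rare species
        if (!any(x > 0 & y > 0)) next
        tested <- tested + 1
        s <- chaoSorensenSimilarity(x, y)
        sj <- 1 - as.numeric(vegan::vegdist(rbind(x, y), "chao"))
        expect_equal(sj, s / (2 - s), tolerance = 1e-10)
    }
    expect_gte(tested, 20)
})

test_that("Raup-Crick closed form equals exhaustive enumeration", {
    expect_equal(raupCrickSimilarity("X", "X", c("X", "Y")), 0.5)
    set.seed(21)
    for (rep in 1:15) {
        poolSize <- sample(3:8, 1)
        pool <- paste0("s", seq_len(poolSize))
        na <- sample(poolSize, 1); nb <- sample(poolSize, 1)
        a <- sample(pool, na); b <- sample(pool, nb)
        j <- length(intersect(a, b))
        got <- if (na == poolSize && nb == poolSize)
            suppressWarnings(raupCrickSimilarity(a, b, pool))
        else raupCrickSimilarity(a, b, pool)
        expect_equal(got, enumRaupCrick(poolSize, na, nb, j),
                     tolerance = 1e-12,
                     info = sprintf("pool=%d na=%d nb=%d j=%d",
                                    poolSize, na, nb, j))
        expect_gte(got, 0); expect_lte(got, 1)
    }
})

test_that("Raup-Crick degenerate cases behave as documented", {
    pool <- c("X", "Y", "Z")
    expect_equal(raupCrickSimilarity("X", "Y", pool), 0)  # j = 0
    expect_warning(z <- raupCrickSimilarity(pool, pool, pool), "entire pool")
    expect_equal(z, 0)
    expect_error(raupCrickSimilarity(c("X", "W"), "X", pool), "absent")
})

test_that("the simulation Raup-Crick variant approximates the closed form under equal weights", {
    pool <- paste0("s", 1:6)
    a <- pool[1:3]; b <- pool[2:5]
    exact <- raupCrickSimilarity(a, b, pool)
    set.seed(4)
    mc <- raupCrickSimilarity(a, b, pool, method = "simulation", nsim = 4000)
    expect_lt(abs(mc - exact), 4 * sqrt(exact * (1 - exact) / 4000) + 0.002)
})

test_that("all four indices are symmetric in their arguments", {
    set.seed(13)
    x <- rpois(10, 2); y <- rpois(10, 3)
    a <- paste0("s", which(x > 0)); b <- paste0("s", which(y > 0))
    pool <- paste0("s", 1:10)
    expect_equal(sorensenSimilarity(a, b), sorensenSimilarity(b, a))
    expect_equal(brayCurtisSimilarity(x / sum(x), y / sum(y)),
                 brayCurtisSimilarity(y / sum(y), x / sum(x)))
    expect_equal(chaoSorensenSimilarity(x, y), chaoSorensenSimilarity(y, x))
    expect_equal(raupCrickSimilarity(a, b, pool),
                 raupCrickSimilarity(b, a, pool))
})

test_that("pairwise matrices equal brute-force per-pair recomputation", {
    set.seed(8)
    m <- matrix(rpois(4 * 12, 3), 4, 12)
    m[, 1] <- c(20, 20, 0, 0)  # some common species
    m[, 2] <- c(0, 15, 15, 15)
    ce <- makeCE(m, bands = c("800", "800", "1000", "1000"))
    rule <- commonSpeciesThreshold(2, 0.95)
    X <- counts(ce)  # species x plots
    totals <- colSums(X)
    commonIdx <- rowSums(X) >= threshold(rule)

    for (idx in c("sorensen", "bray_curtis", "chao_sorensen", "raup_crick")) {
        sim <- pairwiseSimilarity(ce, idx, rule = rule)
        v <- similarityValues(sim)
        expect_identical(dim(v), c(4L, 4L))
        expect_equal(v, t(v))
        for (i in 1:3) for (j in (i + 1):4) {
            expected <- switch(idx,
                sorensen = {
                    Xa <- X[commonIdx, , drop = FALSE]
                    sorensenSimilarity(rownames(Xa)[Xa[, i] > 0],
                                       rownames(Xa)[Xa[, j] > 0])
                },
                bray_curtis = {
                    Xa <- X[commonIdx, , drop = FALSE]
                    brayCurtisSimilarity(Xa[, i] / totals[i],
                                         Xa[, j] / totals[j])
                },
                chao_sorensen = chaoSorensenSimilarity(X[, i], X[, j]),
                raup_crick = raupCrickSimilarity(
                    rownames(X)[X[, i] > 0], rownames(X)[X[, j] > 0],
                    rownames(X)[rowSums(X) > 0]))
            expect_equal(v[i, j], expected, info = paste(idx, i, j))
        }
    }
})

test_that("pairwise similarity refuses mixed transects and counts C(n,2) pairs", {
    set.seed(2)
    ce <- generateAssemblage(syntheticConfig(nSpecies = 200, seed = 2))
    rule <- commonSpeciesThreshold(5, 0.95)
    sim <- pairwiseSimilarity(ce, "sorensen", rule = rule)
    v <- similarityValues(sim)
    expect_equal(sum(upper.tri(v)), choose(20, 2))
    multi <- generateMultiTransect(list(syntheticConfig(nSpecies = 50, seed = 1),
                                        syntheticConfig(nSpecies = 50, seed = 2)))
    expect_error(pairwiseSimilarity(multi, "sorensen", rule = rule),
                 "transect")
})

test_that("identical plots score similarity 1 and conversion flips to distance", {
    m <- rbind(c(5, 3, 14), c(5, 3, 14), c(0, 0, 20))
    ce <- makeCE(m, bands = c("800", "800", "1000"))
    sim <- pairwiseSimilarity(ce, "sorensen",
                              rule = commonSpeciesThreshold(2, 0.95))
    expect_equal(similarityValues(sim)["p1", "p2"], 1)
    d <- as.matrix(asDissimilarity(sim))
    expect_equal(d["p1", "p2"], 0)
    # p1 and p2 contain the whole 3-species pool: degenerate pair flagged
    expect_warning(rc <- pairwiseSimilarity(ce, "raup_crick"), "entire pool")
    expect_true(all(is.na(diag(similarityValues(rc)))))
    expect_warning(asDissimilarity(rc), "non-metric")
})
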