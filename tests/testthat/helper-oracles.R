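# Independent brute-force oracles. Each enumerates the definition directly
# and is kept free of the package's analytic code paths.

# Expected species count in a subsample of n individuals, by enumerating all
# C(N, n) unordered draws of individuals. Feasible for plot totals <= 12.
enumRarefaction <- function(abund, n) {
    individuals <- rep(seq_along(abund), abund)
    draws <- utils::combn(seq_along(individuals), n)
    mean(apply(draws, 2L, function(ix) length(unique(individuals[ix]))))
}

# Distribution of the shared-species count J when two plots of fixed richness
# are drawn at random (equal weights, no replacement) from a pool of
# poolSize species: exhaustive enumeration over all pairs of subsets.
# Returns P(J < j), i.e. the Raup-Crick similarity.
enumRaupCrick <- function(poolSize, na, nb, j) {
    pool <- seq_len(poolSize)
    setsA <- utils::combn(pool, na, simplify = FALSE)
    setsB <- utils::combn(pool, nb, simplify = FALSE)
    shared <- outer(seq_along(setsA), seq_along(setsB),
                    Vectorize(function(i, k)
                        length(intersect(setsA[[i]], setsB[[k]]))))
    mean(shared < j)
}

# All permutations of a vector (used for exact permutation p-values on small
# designs; 6 plots -> 720 permutations).
allPermutations <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
        rest <- allPermutations(v[-i])
        for (r in rest) out[[length(out) + 1L]] <- c(v[i], r)
    }
    out
}

# Scalar IndVal from the definition, one species, one inside/outside split.
refIndval <- function(abund, inside) {
    meanIn <- mean(abund[inside])
    meanOut <- mean(abund[!inside])
    A <- if (meanIn + meanOut == 0) 0 else meanIn / (meanIn + meanOut)
    B <- mean(abund[inside] > 0)
    A * B * 100
}

# Max IndVal over a list of groupings (character band labels) for one species.
refMaxIndval <- function(abund, bandOfPlot, groups) {
    max(vapply(groups, function(g)
        refIndval(abund, bandOfPlot %in% g), numeric(1L)))
}

# Two-pass closed-form OLS slope, independent of stats::lm.
refOlsSlope <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}
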