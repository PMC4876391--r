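#' Sorensen presence/absence similarity
#'
#' \eqn{2|a \cap b| / (|a| + |b|)} on species presence sets. Defined as 0
#' (with a warning) when both sets are empty.
#'
#' @param a,b character vectors of species present at each plot (duplicates
#'   ignored).
#' @return similarity in [0, 1].
#' @export
sorensenSimilarity <- function(a, b) {
    a <- unique(a); b <- unique(b)
    if (length(a) == 0L && length(b) == 0L) {
        warning("both plots are empty; Sorensen similarity set to 0")
        return(0)
    }
    2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Bray-Curtis similarity on proportional abundances
#'
#' \eqn{2 \sum_k \min(p_k, q_k) / \sum_k (p_k + q_k)}. In the elevational
#' pipeline `p` and `q` are the proportional abundances of common species
#' relative to each plot's all-species total, so the vectors need not sum
#' to 1. Defined as 0 (with a warning) when both vectors are all-zero.
#'
#' @param p,q non-negative numeric vectors of equal length, aligned by species.
#' @return similarity in [0, 1].
#' @export
brayCurtisSimilarity <- function(p, q) {
    if (length(p) != length(q))
        stop("p and q must be aligned vectors of equal length")
    if (any(p < 0) || any(q < 0))
        stop("proportions must be non-negative")
    denom <- sum(p) + sum(q)
    if (denom == 0) {
        warning("both plots are empty; Bray-Curtis similarity set to 0")
        return(0)
    }
    2 * sum(pmin(p, q)) / denom
}

#' Chao's abundance-based Sorensen estimator
#'
#' Estimates the Sorensen similarity two plots would show if unseen shared
#' species were accounted for, by boosting the observed shared proportions
#' with a correction based on shared species that are rare (singletons or
#' doubletons) in the other sample:
#' \deqn{U = \sum_{i \in S} \frac{x_i}{n} + \frac{m-1}{m}
#'       \frac{f^+_1}{2 f^+_2} \sum_{i \in S,\, y_i = 1} \frac{x_i}{n}}
#' where \eqn{S} is the set of shared species, \eqn{f^+_1} and \eqn{f^+_2}
#' count shared species that are singletons resp. doubletons in the second
#' sample; \eqn{V} is defined symmetrically. When \eqn{f^+_2 = 0} the divisor
#' uses \eqn{\max(f^+_2, 1)}; \eqn{U} and \eqn{V} are capped at 1. The index
#' is \eqn{2UV/(U+V)}, or 0 when no species is shared.
#'
#' @param x,y abundance vectors aligned by species (all species, not just
#'   common ones).
#' @param n,m sample sizes; default to the vector totals, which is correct
#'   when `x`, `y` cover all species of each plot.
#' @return similarity in [0, 1].
#' @export
chaoSorensenSimilarity <- function(x, y, n = sum(x), m = sum(y)) {
    if (length(x) != length(y))
        stop("x and y must be aligned vectors of equal length")
    if (any(x < 0) || any(y < 0))
        stop("abundances must be non-negative")
    shared <- x > 0 & y > 0
    if (!any(shared))
        return(0)
    U <- .chaoU(x, y, n, m, shared)
    V <- .chaoU(y, x, m, n, shared)
    if (U == 0 && V == 0) return(0)
    2 * U * V / (U + V)
}

.chaoU <- function(x, y, n, m, shared) {
    f1 <- sum(shared & y == 1)
    f2 <- sum(shared & y == 2)
    u <- sum(x[shared]) / n +
        ((m - 1) / m) * (f1 / (2 * max(f2, 1))) * sum(x[shared & y == 1]) / n
    min(u, 1)
}

#' Raup-Crick probabilistic similarity
#'
#' The probability that two plots drawn at random from the species pool (the
#' same pool, each plot keeping its observed species richness, all species
#' equally likely) would share fewer species than the observed pair:
#' \eqn{P(J < j_{obs})} with \eqn{J} hypergeometric. High values indicate more
#' sharing than expected by chance; the index is insensitive to richness
#' differences. The closed-form equal-weight formulation is the default; a
#' Monte-Carlo variant weighting species by occurrence frequency is available
#' via `method = "simulation"`.
#'
#' @param a,b character vectors of species present at each plot.
#' @param pool character vector (or size) of the species pool, typically all
#'   species recorded on the transect.
#' @param method `"hypergeometric"` (closed form) or `"simulation"`.
#' @param weights occurrence-frequency weights named by pool species
#'   (simulation method only; default equal).
#' @param nsim number of random draws for the simulation method.
#' @return similarity in [0, 1]: \eqn{1 - P(J \ge j_{obs})}.
#' @export
raupCrickSimilarity <- function(a, b, pool,
                                method = c("hypergeometric", "simulation"),
                                weights = NULL, nsim = 999) {
    method <- match.arg(method)
    a <- unique(a); b <- unique(b)
    if (is.numeric(pool) && length(pool) == 1L) {
        poolSize <- as.integer(pool)
        poolIds <- NULL
    } else {
        poolIds <- unique(pool)
        poolSize <- length(poolIds)
        if (!all(c(a, b) %in% poolIds))
            stop("plots contain species absent from the pool")
    }
    na <- length(a); nb <- length(b)
    if (na > poolSize || nb > poolSize)
        stop("plot richness exceeds the pool size")
    j <- length(intersect(a, b))
    if (j > min(na, nb))
        stop("shared species exceed the smaller plot richness")
    if (na == poolSize && nb == poolSize)
        warning("both plots contain the entire pool; ",
                "shared count is deterministic and the index is 0")
    if (method == "hypergeometric")
        return(stats::phyper(j - 1, na, poolSize - na, nb))
    if (is.null(poolIds))
        poolIds <- as.character(seq_len(poolSize))
    if (is.null(weights)) {
        w <- rep(1, poolSize)
    } else {
        w <- weights[poolIds]
        if (any(is.na(w)) || any(w <= 0))
            stop("weights must be positive for every pool species")
    }
    draws <- vapply(seq_len(nsim), function(i) {
        sa <- sample(poolIds, na, prob = w)
        sb <- sample(poolIds, nb, prob = w)
        length(intersect(sa, sb))
    }, integer(1L))
    mean(draws < j)
}

#' Pairwise similarity matrix for all plots of one transect
#'
#' Computes all unordered within-transect plot pairs for one index. The
#' canonical index/scope pairing is Sorensen and Bray-Curtis on common species
#' and Chao-Sorensen and Raup-Crick on all species; `scope` defaults
#' accordingly but can be overridden. For `scope = "common"` the matrix `x`
#' must still contain all species: Bray-Curtis proportions are taken relative
#' to the all-species plot totals, and the common set is chosen by `rule`.
#'
#' @param x a [CommunityExperiment-class] whose plots belong to a single
#'   transect (mixing transects is an error, as cross-transect similarities
#'   are near zero and analyses run per transect).
#' @param index similarity index name.
#' @param scope `"common"` or `"all"` (default depends on `index`).
#' @param rule a [CommonSpeciesRule-class]; required when `scope = "common"`.
#' @param rcMethod,rcWeights,rcNsim passed to [raupCrickSimilarity()].
#' @return a [SimilarityMatrix-class].
#' @export
pairwiseSimilarity <- function(x,
                               index = c("sorensen", "bray_curtis",
                                         "chao_sorensen", "raup_crick"),
                               scope = NULL, rule = NULL,
                               rcMethod = "hypergeometric",
                               rcWeights = NULL, rcNsim = 999) {
    index <- match.arg(index)
    cd <- colData(x)
    tr <- NA_character_
    if ("transect" %in% names(cd)) {
        u <- unique(cd$transect)
        if (length(u) > 1L)
            stop("plots from different transects; run per transect ",
                 "(see subsetTransect)")
        tr <- u
    }
    if (is.null(scope))
        scope <- if (index %in% c("sorensen", "bray_curtis")) "common" else "all"
    scope <- match.arg(scope, c("common", "all"))
    m <- counts(x)
    plotTot <- colSums(m)
    if (scope == "common") {
        if (is.null(rule))
            stop("scope = 'common' requires a CommonSpeciesRule")
        m <- counts(filterCommonSpecies(x, rule))
    }
    P <- ncol(m)
    ids <- colnames(m)
    v <- matrix(if (index == "raup_crick") NA_real_ else 1, P, P,
                dimnames = list(ids, ids))
    presence <- lapply(seq_len(P), function(j) rownames(m)[m[, j] > 0])
    pool <- rownames(m)[rowSums(m) > 0]
    for (i in seq_len(P - 1L)) {
        for (j in seq(i + 1L, P)) {
            s <- switch(index,
                sorensen = sorensenSimilarity(presence[[i]], presence[[j]]),
                bray_curtis = brayCurtisSimilarity(m[, i] / plotTot[i],
                                                   m[, j] / plotTot[j]),
                chao_sorensen = chaoSorensenSimilarity(m[, i], m[, j],
                                                       n = plotTot[i],
                                                       m = plotTot[j]),
                raup_crick = raupCrickSimilarity(presence[[i]], presence[[j]],
                                                 pool, method = rcMethod,
                                                 weights = rcWeights,
                                                 nsim = rcNsim))
            v[i, j] <- v[j, i] <- s
        }
    }
    new("SimilarityMatrix", values = v, indexName = index,
        speciesScope = scope, transect = tr)
}

#' @export
setGeneric("similarityValues", function(x) standardGeneric("similarityValues"))
#' @describeIn pairwiseSimilarity extract the symmetric value matrix.
#' @export
setMethod("similarityValues", "SimilarityMatrix", function(x) x@values)

#' @export
setGeneric("indexName", function(x) standardGeneric("indexName"))
#' @describeIn pairwiseSimilarity the index the matrix was built with.
#' @export
setMethod("indexName", "SimilarityMatrix", function(x) x@indexName)

setMethod("show", "SimilarityMatrix", function(object) {
    cat(sprintf("SimilarityMatrix: %s (%s species), %d plots%s\n",
                object@indexName, object@speciesScope, nrow(object@values),
                if (is.na(object@transect)) ""
                else paste0(", transect ", object@transect)))
})

#' Convert similarities to a dissimilarity object
#'
#' `d = 1 - s`, suitable for PERMANOVA or ordination. Raup-Crick similarities
#' are probabilities, not metric similarities; converting them raises a
#' warning (the resulting 'distances' are still accepted downstream, matching
#' common usage).
#'
#' @param x a [SimilarityMatrix-class].
#' @return a `stats::dist` object.
#' @export
asDissimilarity <- function(x) {
    stopifnot(is(x, "SimilarityMatrix"))
    if (x@indexName == "raup_crick")
        warning("Raup-Crick is a non-metric probabilistic measure; ",
                "1 - s is not a metric distance")
    v <- 1 - x@values
    diag(v) <- 0
    stats::as.dist(v)
}
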