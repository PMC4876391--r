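#' One-way PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance for a single grouping
#' factor. With \eqn{N} plots and dissimilarities \eqn{d_{ij}}:
#' \deqn{SS_T = \frac{1}{N} \sum_{i<j} d_{ij}^2, \qquad
#'       SS_W = \sum_g \frac{1}{n_g} \sum_{i<j \in g} d_{ij}^2}
#' \eqn{SS_A = SS_T - SS_W} and pseudo-F \eqn{= (SS_A/df_A)/(SS_W/df_W)} with
#' \eqn{df_A = g - 1}, \eqn{df_W = N - g}. The p-value uses unrestricted
#' permutation of plot labels, counting the observed labelling once:
#' \eqn{p = (1 + \#\{F^* \ge F\}) / (1 + n_{perm})}, hence
#' \eqn{p \ge 1/(n_{perm}+1)}. For a one-way design Type III and sequential
#' sums of squares coincide.
#'
#' @param d a `dist`, symmetric matrix, or [SimilarityMatrix-class] (converted
#'   with [asDissimilarity()]; Raup-Crick input is accepted with a warning).
#' @param groups group (band) label per plot, aligned with `d`'s labels.
#' @param nPermutations number of label permutations (default 4999).
#' @param seed optional integer seed for the permutation stream.
#' @return a [PermanovaResult-class].
#' @export
permanova <- function(d, groups, nPermutations = 4999, seed = NULL) {
    D <- .asDistMatrix(d)
    groups <- as.character(groups)
    N <- nrow(D)
    if (length(groups) != N)
        stop("groups must have one label per plot")
    sizes <- table(groups)
    if (any(sizes < 2L))
        stop("every group needs at least 2 plots; offending group(s): ",
             paste(names(sizes)[sizes < 2L], collapse = ", "))
    g <- length(sizes)
    if (g < 2L)
        stop("at least two groups are required")
    nPermutations <- as.integer(nPermutations)
    if (nPermutations < 1L)
        stop("nPermutations must be >= 1")
    D2 <- D^2
    M <- stats::model.matrix(~ 0 + factor(groups))
    ng <- colSums(M)
    ssT <- sum(D2) / (2 * N)
    ssW_of <- function(M) sum(colSums((D2 %*% M) * M) / (2 * ng))
    ssW <- ssW_of(M)
    ssA <- ssT - ssW
    dfA <- g - 1L
    dfW <- N - g
    Fobs <- (ssA / dfA) / (ssW / dfW)
    if (!is.null(seed)) set.seed(seed)
    exceed <- 0L
    for (k in seq_len(nPermutations)) {
        ssWp <- ssW_of(M[sample.int(N), , drop = FALSE])
        Fp <- ((ssT - ssWp) / dfA) / (ssWp / dfW)
        if (Fp >= Fobs - 1e-10) exceed <- exceed + 1L
    }
    new("PermanovaResult", pseudoF = Fobs, dfAmong = dfA,
        dfWithin = as.integer(dfW), ssAmong = ssA, ssWithin = ssW,
        ssTotal = ssT, pValue = (1 + exceed) / (1 + nPermutations),
        nPermutations = nPermutations,
        pairwise = data.frame())
}

.asDistMatrix <- function(d) {
    if (is(d, "SimilarityMatrix"))
        d <- asDissimilarity(d)
    if (inherits(d, "dist"))
        d <- as.matrix(d)
    if (!is.matrix(d) || nrow(d) != ncol(d))
        stop("d must be a dist object or square matrix")
    if (max(abs(d - t(d))) > 1e-8)
        stop("dissimilarity matrix is not symmetric")
    d
}

#' Pairwise post hoc PERMANOVA comparisons
#'
#' For every pair of groups, a two-group PERMANOVA is run on the submatrix of
#' their plots; the statistic is reported as \eqn{t = \sqrt{pseudo-F}} with its
#' own permutation p-value. Raw p-values are reported (with a Bonferroni
#' column for convenience).
#'
#' @inheritParams permanova
#' @return a data.frame with columns `group1`, `group2`, `t`, `p_value`,
#'   `p_bonferroni`.
#' @export
pairwisePermanova <- function(d, groups, nPermutations = 4999, seed = NULL) {
    D <- .asDistMatrix(d)
    groups <- as.character(groups)
    levs <- unique(groups)
    if (length(levs) < 2L)
        stop("at least two groups are required")
    pairs <- utils::combn(levs, 2L)
    if (!is.null(seed)) set.seed(seed)
    res <- apply(pairs, 2L, function(pr) {
        idx <- groups %in% pr
        r <- permanova(D[idx, idx, drop = FALSE], groups[idx],
                       nPermutations = nPermutations)
        c(t = sqrt(r@pseudoF), p = r@pValue)
    })
    out <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                      t = res["t", ], p_value = res["p", ],
                      stringsAsFactors = FALSE)
    out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
    out
}

setMethod("show", "PermanovaResult", function(object) {
    cat(sprintf(
        "PERMANOVA: pseudo-F = %.4g (df = %d, %d), p = %.4g (%d permutations)\n",
        object@pseudoF, object@dfAmong, object@dfWithin, object@pValue,
        object@nPermutations))
    if (nrow(object@pairwise)) {
        cat("Pairwise comparisons:\n")
        print(object@pairwise, row.names = FALSE)
    }
})

#' @export
setGeneric("pseudoF", function(x) standardGeneric("pseudoF"))
#' @describeIn permanova observed pseudo-F statistic.
#' @param x a `PermanovaResult`.
#' @export
setMethod("pseudoF", "PermanovaResult", function(x) x@pseudoF)

#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @describeIn permanova permutation p-value.
#' @export
setMethod("pValue", "PermanovaResult", function(x) x@pValue)

#' Distance-decay regression of similarity on elevational separation
#'
#' Ordinary least squares of pairwise assemblage similarity on the absolute
#' difference in plot elevation (metres), treating plot pairs as independent
#' observations. The slope measures elevational sensitivity: steeper (more
#' negative) means faster compositional turnover per metre. Raup-Crick input
#' is refused unless `force = TRUE`, as that index is a non-metric
#' probabilistic measure for which a linear decay fit is not meaningful.
#'
#' @param sim a [SimilarityMatrix-class] for the plots of one transect.
#' @param elevations per-plot elevations: a named numeric vector keyed by plot
#'   id, or a [CommunityExperiment-class] carrying `elevation_m` metadata.
#' @param force fit even for Raup-Crick input.
#' @param nPermutations if > 0, a Mantel-style permutation p for the slope is
#'   computed by shuffling plot identities (elevations relative to the
#'   similarity matrix) and comparing absolute slopes; this respects the
#'   non-independence of plot pairs. Off by default: the decay slope is used
#'   descriptively for between-transect comparison.
#' @param seed optional seed for the permutation stream.
#' @return a [DecayFit-class]. Constant similarity yields slope 0 and
#'   \eqn{R^2 = 0} (by convention, since no variance is explained).
#' @export
distanceDecayFit <- function(sim, elevations, force = FALSE,
                             nPermutations = 0, seed = NULL) {
    stopifnot(is(sim, "SimilarityMatrix"))
    if (sim@indexName == "raup_crick" && !force)
        stop("no decay regression for Raup-Crick (non-metric probabilistic ",
             "index); use force = TRUE to override")
    if (is(elevations, "CommunityExperiment")) {
        cd <- colData(elevations)
        if (!"elevation_m" %in% names(cd))
            stop("community carries no elevation_m metadata")
        elevations <- stats::setNames(cd$elevation_m, rownames(cd))
    }
    v <- sim@values
    ids <- rownames(v)
    if (!all(ids %in% names(elevations)))
        stop("elevations missing for plot(s): ",
             paste(setdiff(ids, names(elevations)), collapse = ", "))
    e <- elevations[ids]
    ut <- upper.tri(v)
    dEl <- abs(outer(e, e, "-"))[ut]
    s <- v[ut]
    if (length(unique(dEl)) < 3L)
        stop("fewer than 3 distinct elevational separations; no meaningful fit")
    if (stats::var(s) < .Machine$double.eps) {
        return(new("DecayFit", slope = 0, intercept = mean(s), rSquared = 0,
                   nPairs = length(s), indexName = sim@indexName,
                   pValue = NA_real_))
    }
    fit <- stats::lm(s ~ dEl)
    slope <- unname(stats::coef(fit)[2L])
    pval <- NA_real_
    if (nPermutations > 0) {
        if (!is.null(seed)) set.seed(seed)
        P <- length(e)
        exceed <- 0L
        for (k in seq_len(nPermutations)) {
            ep <- e[sample.int(P)]
            dp <- abs(outer(ep, ep, "-"))[ut]
            if (abs(refSlope <- sum((dp - mean(dp)) * (s - mean(s))) /
                    sum((dp - mean(dp))^2)) >= abs(slope) - 1e-12)
                exceed <- exceed + 1L
        }
        pval <- (1 + exceed) / (1 + nPermutations)
    }
    new("DecayFit",
        slope = slope,
        intercept = unname(stats::coef(fit)[1L]),
        rSquared = summary(fit)$r.squared,
        nPairs = length(s),
        indexName = sim@indexName,
        pValue = pval)
}

setMethod("show", "DecayFit", function(object) {
    cat(sprintf(
        "Distance decay (%s): slope = %.3g per m, intercept = %.3g, R^2 = %.3f (%d pairs)\n",
        object@indexName, object@slope, object@intercept, object@rSquared,
        object@nPairs))
})

#' @export
setGeneric("decaySlope", function(x) standardGeneric("decaySlope"))
#' @describeIn distanceDecayFit fitted slope (similarity per metre).
#' @param x a `DecayFit`.
#' @export
setMethod("decaySlope", "DecayFit", function(x) x@slope)
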