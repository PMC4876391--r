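#' Abundance-standardized (rarefied) species richness
#'
#' Analytic individual-based rarefaction (Hurlbert): the expected number of
#' species in a random subsample of `nStandard` individuals from a plot with
#' total \eqn{N} and species abundances \eqn{N_i} is
#' \deqn{E[S] = \sum_i \left[1 - \binom{N - N_i}{n} / \binom{N}{n}\right]}
#' evaluated exactly in log space. This is the expectation of the resampled
#' accumulation curve, read off at a standard abundance so plots with unequal
#' sampling can be compared.
#'
#' @param x a [CommunityExperiment-class].
#' @param nStandard rarefaction depth (individuals); must not exceed the
#'   smallest plot total unless `skipUndersampled = TRUE`.
#' @param skipUndersampled if `TRUE`, plots with fewer than `nStandard`
#'   individuals get `NA` instead of raising an error.
#' @return a data.frame with columns `plot_id`, `n_standard`,
#'   `expected_species`, `observed_species`, `plot_total`.
#' @examples
#' ce <- CommunityExperiment(matrix(c(3L, 1L), 2,
#'     dimnames = list(c("A", "B"), "p1")))
#' rarefiedRichness(ce, 2)$expected_species  # 1.5
#' @export
rarefiedRichness <- function(x, nStandard, skipUndersampled = FALSE) {
    nStandard <- as.integer(nStandard)
    if (length(nStandard) != 1L || is.na(nStandard) || nStandard < 1L)
        stop("nStandard must be a single positive integer")
    m <- counts(x)
    totals <- colSums(m)
    short <- totals < nStandard
    if (any(short) && !skipUndersampled)
        stop("nStandard exceeds the total abundance of plot(s): ",
             paste(colnames(m)[short], collapse = ", "))
    es <- vapply(seq_len(ncol(m)), function(j) {
        if (short[j]) return(NA_real_)
        .hurlbert(m[, j], totals[j], nStandard)
    }, numeric(1L))
    data.frame(plot_id = colnames(m),
               n_standard = nStandard,
               expected_species = es,
               observed_species = colSums(m > 0),
               plot_total = totals,
               row.names = NULL,
               stringsAsFactors = FALSE)
}

.hurlbert <- function(abund, N, n) {
    Ni <- abund[abund > 0]
    # lchoose(N - Ni, n) is -Inf when N - Ni < n: the species is certain to
    # appear and its term is exactly 1
    sum(1 - exp(lchoose(N - Ni, n) - lchoose(N, n)))
}

#' Minimum abundance for reliable detection ('common' species rule)
#'
#' Under the detection model in which each of `nPlots` equally likely plots
#' receives each individual independently, a species with total abundance
#' \eqn{N} is seen in a given plot with probability
#' \eqn{P = 1 - (1 - 1/n)^N}. The rule returns the smallest integer \eqn{N}
#' with \eqn{P \ge} `targetProbability`. For the canonical design of 5 plots
#' per band and a 95% target the threshold is 14 individuals.
#'
#' @param nPlots number of plots per habitat unit (>= 1).
#' @param targetProbability required detection probability, strictly in (0, 1).
#' @return a [CommonSpeciesRule-class].
#' @examples
#' threshold(commonSpeciesThreshold(5, 0.95))  # 14
#' @export
commonSpeciesThreshold <- function(nPlots, targetProbability = 0.95) {
    nPlots <- as.integer(nPlots)
    if (length(nPlots) != 1L || is.na(nPlots) || nPlots < 1L)
        stop("nPlots must be a single integer >= 1")
    if (!is.numeric(targetProbability) || length(targetProbability) != 1L ||
        targetProbability <= 0 || targetProbability >= 1)
        stop("targetProbability must lie strictly in (0, 1)")
    if (nPlots == 1L) {
        thr <- 1L
    } else {
        # closed form, then an integer scan to guard against rounding at the
        # boundary
        thr <- max(1L, as.integer(ceiling(log1p(-targetProbability) /
                                          log1p(-1 / nPlots))) - 1L)
        while (1 - (1 - 1 / nPlots)^thr < targetProbability)
            thr <- thr + 1L
    }
    new("CommonSpeciesRule", nPlots = nPlots,
        targetProbability = targetProbability, threshold = thr)
}

#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))
#' @describeIn commonSpeciesThreshold extract the integer threshold.
#' @param x a `CommonSpeciesRule`.
#' @export
setMethod("threshold", "CommonSpeciesRule", function(x) x@threshold)

setMethod("show", "CommonSpeciesRule", function(object) {
    cat(sprintf(
        "CommonSpeciesRule: N >= %d (detection P >= %.2f over n = %d plots)\n",
        object@threshold, object@targetProbability, object@nPlots))
})

#' Retain only 'common' species
#'
#' Keeps species whose total abundance within a transect meets the rule's
#' threshold (inclusive: a species with exactly the threshold abundance is
#' common). Commonness is assessed within each transect separately; with
#' multiple transects present a species is retained wherever it is common in
#' the transect its records come from (species pools are typically
#' transect-specific). Plot columns are always preserved.
#'
#' @param x a [CommunityExperiment-class].
#' @param rule a [CommonSpeciesRule-class] from [commonSpeciesThreshold()].
#' @return a `CommunityExperiment` restricted to common species.
#' @export
filterCommonSpecies <- function(x, rule) {
    stopifnot(is(rule, "CommonSpeciesRule"))
    cd <- colData(x)
    m <- counts(x)
    if ("transect" %in% names(cd)) {
        keep <- rep(FALSE, nrow(m))
        for (tr in unique(cd$transect)) {
            tot <- rowSums(m[, cd$transect == tr, drop = FALSE])
            keep <- keep | tot >= rule@threshold
        }
    } else {
        keep <- rowSums(m) >= rule@threshold
    }
    if (!any(keep))
        warning("no species meets the commonness threshold of ",
                rule@threshold)
    x[keep, ]
}
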