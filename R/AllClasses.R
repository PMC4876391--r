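#' @import methods
#' @importFrom BiocGenerics counts
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   colData<- rowData rowData<-
NULL

#' Plot-by-species community container
#'
#' `CommunityExperiment` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' for community abundance data: rows are species (or morphospecies), columns
#' are sampling plots, and the `"counts"` assay holds non-negative integer
#' abundances. Plot metadata (transect, elevational band, elevation in metres,
#' optional vertical stratum) lives in `colData`; species-level attributes
#' (e.g. the simulated niche truth) live in `rowData`.
#'
#' @section Validity:
#' Counts must be finite, integer-valued and non-negative; row (species) and
#' column (plot) names must be present and unique. When the metadata columns
#' `transect`, `band` or `elevation_m` are present they are type-checked, and
#' `elevation_m` must be finite.
#'
#' @seealso [CommunityExperiment()] for construction,
#'   [readCommunityCSV()] for file input.
#' @export
setClass("CommunityExperiment", contains = "SummarizedExperiment")

setValidity("CommunityExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% names(assays(object)))
        return("assay 'counts' is required")
    x <- assay(object, "counts")
    if (!is.numeric(x))
        return("counts must be numeric")
    if (any(!is.finite(x)))
        msg <- c(msg, "counts contain non-finite values")
    else {
        if (any(x < 0))
            msg <- c(msg, "counts must be non-negative")
        if (any(x != round(x)))
            msg <- c(msg, "counts must be integer-valued")
    }
    if (is.null(rownames(object)) || is.null(colnames(object)))
        msg <- c(msg, "species (row) and plot (column) names are required")
    else {
        if (anyDuplicated(rownames(object)))
            msg <- c(msg, "duplicate species identifiers")
        if (anyDuplicated(colnames(object)))
            msg <- c(msg, "duplicate plot identifiers")
    }
    cd <- colData(object)
    if ("elevation_m" %in% names(cd) &&
        (!is.numeric(cd$elevation_m) || any(!is.finite(cd$elevation_m))))
        msg <- c(msg, "elevation_m must be finite numeric")
    for (col in c("transect", "band"))
        if (col %in% names(cd) && !is.character(cd[[col]]))
            msg <- c(msg, sprintf("column '%s' must be character", col))
    if (length(msg)) msg else TRUE
})

#' Rule selecting 'common' species by detection probability
#'
#' Encapsulates the minimum total abundance a species needs, given `nPlots`
#' equally likely plots, to be detected in at least one plot with probability
#' at least `targetProbability` under the detection model
#' \eqn{P = 1 - (1 - 1/n)^N}. See [commonSpeciesThreshold()].
#'
#' @slot nPlots integer, number of plots per habitat unit.
#' @slot targetProbability detection probability in (0, 1).
#' @slot threshold smallest integer abundance meeting the target.
#' @export
setClass("CommonSpeciesRule",
    representation(nPlots = "integer",
                   targetProbability = "numeric",
                   threshold = "integer"))

setValidity("CommonSpeciesRule", function(object) {
    if (length(object@nPlots) != 1L || object@nPlots < 1L)
        return("nPlots must be a single integer >= 1")
    p <- object@targetProbability
    if (length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
        return("targetProbability must lie strictly in (0, 1)")
    if (length(object@threshold) != 1L || object@threshold < 1L)
        return("threshold must be a single integer >= 1")
    TRUE
})

#' Candidate elevational-band groupings for indicator analysis
#'
#' All contiguous runs of one or more elevational bands, excluding the run
#' covering the whole transect. For `B` bands there are `B(B+1)/2 - 1`
#' groupings (nine for the canonical four-band transect). Groups are ordered
#' by span (fewest bands first) and then by elevation, which fixes the
#' tie-breaking order used by [bestIndicator()].
#'
#' @slot bands character, band labels in increasing elevation.
#' @slot elevations numeric, mean elevation of each band (metres).
#' @slot groups list of character vectors, each a contiguous run of bands.
#' @export
setClass("GroupingScheme",
    representation(bands = "character",
                   elevations = "numeric",
                   groups = "list"))

setValidity("GroupingScheme", function(object) {
    B <- length(object@bands)
    if (B < 2L)
        return("at least two bands are required")
    if (length(object@elevations) != B)
        return("elevations must match bands")
    if (is.unsorted(object@elevations, strictly = TRUE))
        return("bands must be ordered by strictly increasing elevation")
    if (length(object@groups) != B * (B + 1L) / 2L - 1L)
        return("wrong number of candidate groupings")
    TRUE
})

#' Pairwise plot-similarity matrix
#'
#' Symmetric matrix of pairwise assemblage similarities in [0, 1] for one
#' index, with the species scope recorded (`"common"` for Sorensen and
#' Bray-Curtis, `"all"` for Chao-Sorensen and Raup-Crick). The diagonal is 1
#' except for Raup-Crick, where self-similarity is not meaningful and is NA.
#'
#' @slot values numeric symmetric matrix with plot ids as dimnames.
#' @slot indexName one of `"sorensen"`, `"bray_curtis"`, `"chao_sorensen"`,
#'   `"raup_crick"`.
#' @slot speciesScope `"common"` or `"all"`.
#' @slot transect transect label the plots belong to (may be `NA`).
#' @export
setClass("SimilarityMatrix",
    representation(values = "matrix",
                   indexName = "character",
                   speciesScope = "character",
                   transect = "character"))

.SIM_INDICES <- c("sorensen", "bray_curtis", "chao_sorensen", "raup_crick")

setValidity("SimilarityMatrix", function(object) {
    v <- object@values
    if (nrow(v) != ncol(v) || is.null(rownames(v)) ||
        !identical(rownames(v), colnames(v)))
        return("values must be square with matching dimnames")
    if (!isTRUE(all.equal(v, t(v), tolerance = 1e-12, check.attributes = FALSE)))
        return("values must be symmetric")
    off <- v[row(v) != col(v)]
    if (any(!is.na(off) & (off < -1e-12 | off > 1 + 1e-12)))
        return("off-diagonal similarities must lie in [0, 1]")
    if (!object@indexName %in% .SIM_INDICES)
        return(sprintf("indexName must be one of %s",
                       paste(.SIM_INDICES, collapse = ", ")))
    if (!object@speciesScope %in% c("common", "all"))
        return("speciesScope must be 'common' or 'all'")
    if (object@indexName != "raup_crick" && any(abs(diag(v) - 1) > 1e-12))
        return("diagonal must equal 1 for this index")
    TRUE
})

#' One-way PERMANOVA result
#'
#' @slot pseudoF observed pseudo-F statistic.
#' @slot dfAmong,dfWithin degrees of freedom (groups - 1, plots - groups).
#' @slot ssAmong,ssWithin,ssTotal sums of squared dissimilarities.
#' @slot pValue permutation p-value; the observed labelling counts once, so
#'   `pValue >= 1 / (nPermutations + 1)`.
#' @slot nPermutations number of unrestricted label permutations.
#' @slot pairwise data.frame of pairwise post hoc tests (may have 0 rows):
#'   columns group1, group2, t, p_value, p_bonferroni.
#' @export
setClass("PermanovaResult",
    representation(pseudoF = "numeric", dfAmong = "integer",
                   dfWithin = "integer", ssAmong = "numeric",
                   ssWithin = "numeric", ssTotal = "numeric",
                   pValue = "numeric", nPermutations = "integer",
                   pairwise = "data.frame"))

#' Distance-decay regression fit
#'
#' Ordinary least squares of pairwise similarity on pairwise elevational
#' separation (metres). A steeper (more negative) slope indicates an
#' assemblage more sensitive to elevation.
#'
#' @slot slope similarity change per metre of elevational separation.
#' @slot intercept fitted similarity at zero separation.
#' @slot rSquared coefficient of determination (0 for constant similarity).
#' @slot nPairs number of plot pairs fitted.
#' @slot indexName similarity index the fit is based on.
#' @slot pValue optional Mantel-style permutation p for the slope (`NA`
#'   unless requested; plot pairs are not independent, so the OLS p would be
#'   anti-conservative).
#' @export
setClass("DecayFit",
    representation(slope = "numeric", intercept = "numeric",
                   rSquared = "numeric", nPairs = "integer",
                   indexName = "character", pValue = "numeric"))

#' Null-model effect size for the significant-indicator count
#'
#' @slot observedCount number of significant indicator species in the data.
#' @slot nullCounts significant-indicator counts from datasets with plots
#'   shuffled across bands.
#' @slot effectSize (observed - mean(null)) / sd(null); `NA` (flagged via
#'   `undefined`) when the null counts have zero spread.
#' @slot undefined TRUE when sd(null) == 0.
#' @slot nNull number of null datasets.
#' @slot alpha significance level used for individual indicators.
#' @export
setClass("EffectSizeResult",
    representation(observedCount = "integer", nullCounts = "integer",
                   effectSize = "numeric", undefined = "logical",
                   nNull = "integer", alpha = "numeric"))

#' Configuration of the synthetic assemblage generator
#'
#' Species have Gaussian elevational niches: the expected count of species
#' \eqn{s} at plot \eqn{p} is \eqn{peak_s \exp(-(e_p - o_s)^2 / (2\sigma_s^2))}
#' where \eqn{o_s} is the niche optimum and \eqn{\sigma_s} the niche width.
#' Peak abundances follow a log-normal species abundance distribution; realized
#' counts are drawn from a Poisson or negative-binomial detection model.
#'
#' @slot nSpecies number of species in the regional pool of the transect.
#' @slot bandElevations increasing band elevations (metres a.s.l.).
#' @slot plotsPerBand replicate plots per band (>= 2).
#' @slot nicheWidthSigma Gaussian niche SD (metres, > 0).
#' @slot nicheCenterSpread metres beyond the gradient ends over which niche
#'   optima are placed uniformly.
#' @slot sadMeanlog,sadSdlog log-normal parameters of peak expected abundance.
#' @slot detection `"nbinom"` or `"poisson"`.
#' @slot dispersionK negative-binomial dispersion (size) parameter.
#' @slot elevationJitter half-width (metres) of the uniform jitter applied to
#'   plot elevations around their band elevation.
#' @slot seed integer RNG seed.
#' @export
setClass("SyntheticConfig",
    representation(nSpecies = "integer", bandElevations = "numeric",
                   plotsPerBand = "integer", nicheWidthSigma = "numeric",
                   nicheCenterSpread = "numeric", sadMeanlog = "numeric",
                   sadSdlog = "numeric", detection = "character",
                   dispersionK = "numeric", elevationJitter = "numeric",
                   seed = "integer"))

setValidity("SyntheticConfig", function(object) {
    msg <- character()
    if (object@nSpecies < 1L)
        msg <- c(msg, "nSpecies must be >= 1")
    if (length(object@bandElevations) < 2L ||
        is.unsorted(object@bandElevations, strictly = TRUE))
        msg <- c(msg, "bandElevations must be >= 2 strictly increasing values")
    if (object@plotsPerBand < 2L)
        msg <- c(msg, "plotsPerBand must be >= 2")
    if (!is.finite(object@nicheWidthSigma) || object@nicheWidthSigma <= 0)
        msg <- c(msg, "nicheWidthSigma must be > 0")
    if (object@nicheCenterSpread < 0)
        msg <- c(msg, "nicheCenterSpread must be >= 0")
    if (!object@detection %in% c("nbinom", "poisson"))
        msg <- c(msg, "detection must be 'nbinom' or 'poisson'")
    if (object@detection == "nbinom" &&
        (!is.finite(object@dispersionK) || object@dispersionK <= 0))
        msg <- c(msg, "dispersionK must be > 0 for nbinom detection")
    if (object@elevationJitter < 0)
        msg <- c(msg, "elevationJitter must be >= 0")
    if (length(msg)) msg else TRUE
})
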