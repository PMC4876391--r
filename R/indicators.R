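#' Candidate elevational-band groupings
#'
#' Every contiguous run of elevational bands, from single bands up to runs of
#' all-but-one band; the run spanning the whole transect is excluded. For
#' \eqn{B} bands this yields \eqn{B(B+1)/2 - 1} candidate groupings (nine for
#' four bands: 4 singles, 3 adjacent pairs, 2 triples). Groups are ordered by
#' span then elevation, which defines the deterministic tie-break used by
#' [bestIndicator()] (fewest bands, then lowest elevation).
#'
#' @param bands band labels in increasing elevation, or a
#'   [CommunityExperiment-class] with band/elevation metadata (ordering then
#'   derives from mean `elevation_m`).
#' @param elevations mean elevation per band (required when `bands` is a
#'   character vector; defaults to the rank order).
#' @return a [GroupingScheme-class].
#' @examples
#' length(groupings(candidateGroupings(c("800", "1000", "1200", "1400")))) # 9
#' @export
candidateGroupings <- function(bands, elevations = NULL) {
    if (is(bands, "CommunityExperiment")) {
        x <- bands
        bands <- bandsOrdered(x)
        cd <- colData(x)
        elevations <- as.numeric(tapply(cd$elevation_m, cd$band,
                                        mean)[bands])
    } else if (is.null(elevations)) {
        elevations <- seq_along(bands)
    }
    bands <- as.character(bands)
    B <- length(bands)
    if (B < 2L)
        stop("at least two bands are required to form candidate groupings")
    groups <- list()
    for (span in seq_len(B - 1L))
        for (start in seq_len(B - span + 1L))
            groups[[length(groups) + 1L]] <- bands[start:(start + span - 1L)]
    names(groups) <- vapply(groups, function(g) {
        if (length(g) == 1L) g else paste(g[1L], g[length(g)], sep = "-")
    }, character(1L))
    new("GroupingScheme", bands = bands, elevations = as.numeric(elevations),
        groups = groups)
}

#' @export
setGeneric("groupings", function(x) standardGeneric("groupings"))
#' @describeIn candidateGroupings list of candidate groupings (character
#'   vectors of band labels).
#' @param x a `GroupingScheme`.
#' @export
setMethod("groupings", "GroupingScheme", function(x) x@groups)

setMethod("show", "GroupingScheme", function(object) {
    cat(sprintf("GroupingScheme: %d bands (%s), %d candidate groupings\n",
                length(object@bands), paste(object@bands, collapse = " < "),
                length(object@groups)))
})

# Internal: band index per plot, aligned with scheme@bands
.bandIndex <- function(x, scheme) {
    cd <- colData(x)
    if (!"band" %in% names(cd))
        stop("plot metadata with 'band' is required")
    idx <- match(cd$band, scheme@bands)
    if (any(is.na(idx)))
        stop("plot band(s) absent from the grouping scheme: ",
             paste(unique(cd$band[is.na(idx)]), collapse = ", "))
    idx
}

# Internal: B x G membership of bands in groups
.bandMembership <- function(scheme) {
    B <- length(scheme@bands)
    G <- length(scheme@groups)
    BM <- matrix(0, B, G, dimnames = list(scheme@bands, names(scheme@groups)))
    for (g in seq_len(G))
        BM[match(scheme@groups[[g]], scheme@bands), g] <- 1
    BM
}

# Internal: S x G matrix of indicator values (percent) for every species and
# candidate grouping, given the plot-to-band assignment bandIdx.
.indvalMatrix <- function(X, Occ, rowTot, P, BM, bandIdx) {
    Z <- BM[bandIdx, , drop = FALSE]           # plots x groups
    nIn <- colSums(Z)
    sumIn <- X %*% Z
    meanIn <- sweep(sumIn, 2L, nIn, "/")
    meanOut <- sweep(rowTot - sumIn, 2L, P - nIn, "/")
    denom <- meanIn + meanOut
    A <- ifelse(denom > 0, meanIn / denom, 0)  # specificity
    B <- sweep(Occ %*% Z, 2L, nIn, "/")        # fidelity
    A * B * 100
}

.indvalSetup <- function(x, scheme) {
    X <- counts(x)
    list(X = X, Occ = (X > 0) * 1, rowTot = rowSums(X), P = ncol(X),
         BM = .bandMembership(scheme), bandIdx = .bandIndex(x, scheme))
}

#' Indicator value of every species for one band grouping
#'
#' Dufrene-Legendre indicator value against the binary partition
#' {inside the grouping, outside it}: specificity
#' \eqn{A = \bar{x}_{in} / (\bar{x}_{in} + \bar{x}_{out})} (mean abundance
#' inside vs outside; 0 when the species is absent everywhere), fidelity
#' \eqn{B} = proportion of inside plots occupied, and
#' \eqn{IndVal = A \cdot B \cdot 100}. A species scores 100 exactly when it
#' occurs in every plot of the grouping and nowhere outside it. IndVal is
#' invariant to rescaling a species' counts by a positive constant.
#'
#' @param x a [CommunityExperiment-class], normally already restricted to
#'   common species (see [filterCommonSpecies()]).
#' @param grouping character vector of band labels forming the group.
#' @param scheme optional [GroupingScheme-class]; derived from `x` if missing.
#' @return named numeric vector of indicator values (percent) per species.
#' @export
indicatorValue <- function(x, grouping, scheme = NULL) {
    if (is.null(scheme))
        scheme <- candidateGroupings(x)
    if (!all(grouping %in% scheme@bands))
        stop("unknown band(s) in grouping")
    st <- .indvalSetup(x, scheme)
    if (!any(st$bandIdx %in% match(grouping, scheme@bands)))
        stop("the grouping contains no plots")
    BM1 <- matrix(0, length(scheme@bands), 1L)
    BM1[match(grouping, scheme@bands), 1L] <- 1
    iv <- .indvalMatrix(st$X, st$Occ, st$rowTot, st$P, BM1, st$bandIdx)
    stats::setNames(iv[, 1L], rownames(st$X))
}

#' Best grouping per species
#'
#' For every species, the candidate grouping attaining the highest indicator
#' value. Ties are broken deterministically towards the grouping spanning
#' fewer bands and, among equal spans, the lower elevation (the ordering of
#' [candidateGroupings()]).
#'
#' @inheritParams indicatorValue
#' @param scheme a [GroupingScheme-class]; derived from `x` if missing.
#' @return data.frame with columns `species_id`, `best_group`, `indval`.
#' @export
bestIndicator <- function(x, scheme = NULL) {
    if (is.null(scheme))
        scheme <- candidateGroupings(x)
    st <- .indvalSetup(x, scheme)
    iv <- .indvalMatrix(st$X, st$Occ, st$rowTot, st$P, st$BM, st$bandIdx)
    best <- max.col(iv, ties.method = "first")
    data.frame(species_id = rownames(st$X),
               best_group = names(scheme@groups)[best],
               indval = iv[cbind(seq_len(nrow(iv)), best)],
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Permutation significance of the best indicator value
#'
#' Tests each species' maximum indicator value against its null distribution
#' under random reassignment of plots to bands (plot labels permuted, band
#' sizes preserved). The observed assignment counts once:
#' \eqn{p = (1 + \#\{max IndVal^* \ge max IndVal\}) / (1 + n_{perm})}.
#' Benjamini-Hochberg q-values are added for convenience; the protocol itself
#' applies no multiplicity correction.
#'
#' @inheritParams bestIndicator
#' @param nPermutations permutations of the plot-to-band assignment
#'   (default 999).
#' @param seed optional integer seed.
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @return data.frame with columns `species_id`, `best_group`, `indval`,
#'   `p_value`, `q_value`, `significant`; attributes `alpha` and
#'   `nPermutations`.
#' @export
indicatorSignificance <- function(x, scheme = NULL, nPermutations = 999,
                                  seed = NULL, alpha = 0.05) {
    if (is.null(scheme))
        scheme <- candidateGroupings(x)
    nPermutations <- as.integer(nPermutations)
    if (nPermutations < 1L)
        stop("nPermutations must be >= 1")
    st <- .indvalSetup(x, scheme)
    if (!is.null(seed)) set.seed(seed)
    res <- .significanceCore(st, nPermutations)
    best <- res$best
    out <- data.frame(species_id = rownames(st$X),
                      best_group = names(scheme@groups)[best],
                      indval = res$obs,
                      p_value = res$p,
                      q_value = stats::p.adjust(res$p, "BH"),
                      significant = res$p <= alpha,
                      row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "alpha") <- alpha
    attr(out, "nPermutations") <- nPermutations
    out
}

# Shared permutation engine: observed max IndVal per species, argmax, and the
# exceedance count over nPermutations shuffles of the plot-to-band assignment.
.significanceCore <- function(st, nPermutations) {
    iv <- .indvalMatrix(st$X, st$Occ, st$rowTot, st$P, st$BM, st$bandIdx)
    best <- max.col(iv, ties.method = "first")
    obs <- iv[cbind(seq_len(nrow(iv)), best)]
    exceed <- integer(length(obs))
    for (k in seq_len(nPermutations)) {
        ivp <- .indvalMatrix(st$X, st$Occ, st$rowTot, st$P, st$BM,
                             st$bandIdx[sample.int(st$P)])
        mp <- max.col(ivp, ties.method = "first")
        vp <- ivp[cbind(seq_len(nrow(ivp)), mp)]
        exceed <- exceed + (vp >= obs - 1e-9)
    }
    list(obs = obs, best = best,
         p = (1 + exceed) / (1 + nPermutations))
}

#' Tally significant indicator species
#'
#' @param results output of [indicatorSignificance()].
#' @return list with `total` (count of significant species) and `proportions`
#'   (share of the significant species indicating each best grouping).
#' @export
countSignificant <- function(results) {
    sig <- results[results$significant, , drop = FALSE]
    total <- nrow(sig)
    props <- if (total == 0L) numeric(0)
             else sort(table(sig$best_group) / total, decreasing = TRUE)
    list(total = total, proportions = props)
}

#' Null-model standardized effect size of the significant-indicator count
#'
#' The number of significant indicator species depends on the species pool, so
#' counts are not comparable across transects directly. This procedure
#' compares the observed count against counts from null datasets in which the
#' plot-to-band assignment is shuffled; the full significance protocol
#' (including its inner permutation test) is re-run on every null dataset.
#' \deqn{ES = (observed - \overline{null}) / sd(null)}
#' ES is 0 when the observed count equals the null mean and flagged undefined
#' when the null counts have zero spread.
#'
#' Each null replicate gets its own deterministic seed derived from `seed`
#' (counter-based), so results are reproducible and replicates independent.
#' The inner significance test inside null datasets may use fewer permutations
#' than the observed dataset (`innerPermutations`); the effect size is robust
#' to the inner-permutation count.
#'
#' @inheritParams indicatorSignificance
#' @param nNull number of shuffled null datasets (default 999).
#' @param nPermutations permutations for the observed dataset's significance
#'   test (default 999).
#' @param innerPermutations permutations for the significance test inside each
#'   null dataset (default 199).
#' @return an [EffectSizeResult-class].
#' @export
effectSizeNullModel <- function(x, scheme = NULL, nNull = 999,
                                nPermutations = 999, innerPermutations = 199,
                                seed = NULL, alpha = 0.05) {
    if (is.null(scheme))
        scheme <- candidateGroupings(x)
    nNull <- as.integer(nNull)
    if (nNull < 2L)
        stop("nNull must be >= 2")
    st <- .indvalSetup(x, scheme)
    if (!is.null(seed)) set.seed(seed)
    obsRes <- .significanceCore(st, as.integer(nPermutations))
    observed <- sum(obsRes$p <= alpha)
    nullCounts <- integer(nNull)
    for (i in seq_len(nNull)) {
        if (!is.null(seed)) set.seed(seed + i)
        stNull <- st
        stNull$bandIdx <- st$bandIdx[sample.int(st$P)]
        nullRes <- .significanceCore(stNull, as.integer(innerPermutations))
        nullCounts[i] <- sum(nullRes$p <= alpha)
    }
    sdNull <- stats::sd(nullCounts)
    undefined <- sdNull == 0
    es <- if (undefined) NA_real_ else (observed - mean(nullCounts)) / sdNull
    new("EffectSizeResult", observedCount = as.integer(observed),
        nullCounts = nullCounts, effectSize = es, undefined = undefined,
        nNull = nNull, alpha = alpha)
}

setMethod("show", "EffectSizeResult", function(object) {
    cat(sprintf(
        "Indicator effect size: observed = %d significant species,\n  null = %.2f +/- %.2f over %d datasets, ES = %s\n",
        object@observedCount, mean(object@nullCounts),
        stats::sd(object@nullCounts), object@nNull,
        if (object@undefined) "undefined (sd(null) = 0)"
        else sprintf("%.3f", object@effectSize)))
})

#' @export
setGeneric("effectSize", function(x) standardGeneric("effectSize"))
#' @describeIn effectSizeNullModel standardized effect size (NA when
#'   undefined).
#' @param x an `EffectSizeResult`.
#' @export
setMethod("effectSize", "EffectSizeResult", function(x) x@effectSize)

#' @export
setGeneric("observedCount", function(x) standardGeneric("observedCount"))
#' @describeIn effectSizeNullModel observed significant-indicator count.
#' @export
setMethod("observedCount", "EffectSizeResult", function(x) x@observedCount)
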