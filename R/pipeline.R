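#' Run the full elevational-sensitivity pipeline
#'
#' Orchestrates the complete analysis for each transect of a dataset:
#' stratum pooling, abundance-standardized richness, common-species selection,
#' the four pairwise similarity matrices, PERMANOVA with pairwise post hoc
#' tests, distance-decay regression (all indices except Raup-Crick), the
#' indicator-value protocol and its null-model effect size. Per-transect
#' tables are written as CSV, scalar summaries as JSON, and a run summary
#' ranks transects by decay-slope magnitude and effect size. All randomness is
#' derived from `seed`; re-running with the same inputs and seed reproduces
#' every output byte-identically.
#'
#' @param x a [CommunityExperiment-class] with plot metadata, or `NULL` to
#'   simulate.
#' @param configs list of [SyntheticConfig-class] used when `x` is `NULL`
#'   (passed to [generateMultiTransect()], or [generateAssemblage()] when of
#'   length 1).
#' @param communityCSV,metadataCSV alternatively, file paths to read.
#' @param outDir output directory (created if needed).
#' @param nStandard requested rarefaction depth; capped at the smallest plot
#'   total of each transect (default 364).
#' @param commonP detection probability of the common-species rule
#'   (default 0.95).
#' @param indices similarity indices to compute.
#' @param nPermutations PERMANOVA permutations (default 4999).
#' @param indicatorPermutations permutations for the observed indicator test
#'   (default 999).
#' @param nNull null datasets for the effect size (default 999).
#' @param innerPermutations indicator permutations inside null datasets
#'   (default 199).
#' @param alpha indicator significance level (default 0.05).
#' @param seed master seed (default 1).
#' @param writeFigures also write simple SVG decay scatter and effect-size
#'   figures (requires cairo support; skipped with a message otherwise).
#' @return (invisibly) a named list per transect with the result objects plus
#'   `$summary`.
#' @export
runPipeline <- function(x = NULL, configs = NULL, communityCSV = NULL,
                        metadataCSV = NULL, outDir = ".",
                        nStandard = 364, commonP = 0.95,
                        indices = c("sorensen", "bray_curtis",
                                    "chao_sorensen", "raup_crick"),
                        nPermutations = 4999, indicatorPermutations = 999,
                        nNull = 999, innerPermutations = 199,
                        alpha = 0.05, seed = 1, writeFigures = FALSE) {
    if (is.null(x)) {
        if (!is.null(configs)) {
            x <- if (length(configs) == 1L)
                     generateAssemblage(configs[[1L]])
                 else generateMultiTransect(configs)
            message("simulate: generated ", ncol(x), " plots, ", nrow(x),
                    " species")
        } else if (!is.null(communityCSV)) {
            x <- readCommunityCSV(communityCSV)
            if (is.null(metadataCSV))
                stop("metadataCSV is required with communityCSV input")
            x <- attachPlotData(x, readMetadataCSV(metadataCSV))
            message("ingest: read ", ncol(x), " plots, ", nrow(x), " species")
        } else {
            stop("provide x, configs, or communityCSV + metadataCSV")
        }
    }
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    x <- poolStrata(x)
    trs <- transects(x)
    if (length(trs) == 1L && is.na(trs))
        stop("plot metadata with a 'transect' column is required")
    results <- list()
    for (ti in seq_along(trs)) {
        tr <- trs[ti]
        results[[tr]] <- .runTransect(
            subsetTransect(x, tr), tr, outDir,
            nStandard = nStandard, commonP = commonP, indices = indices,
            nPermutations = nPermutations,
            indicatorPermutations = indicatorPermutations,
            nNull = nNull, innerPermutations = innerPermutations,
            alpha = alpha, seed = seed + 1000L * ti,
            writeFigures = writeFigures)
    }
    summary <- .pipelineSummary(results, seed)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    message("summary written to ", file.path(outDir, "summary.json"))
    results$summary <- summary
    invisible(results)
}

.runTransect <- function(xt, tr, outDir, nStandard, commonP, indices,
                         nPermutations, indicatorPermutations, nNull,
                         innerPermutations, alpha, seed, writeFigures) {
    message(sprintf("[%s] %d plots, %d species, %d individuals", tr,
                    ncol(xt), nrow(xt), sum(counts(xt))))
    cd <- colData(xt)
    depth <- min(nStandard, min(plotTotals(xt)))
    if (depth < nStandard)
        message(sprintf(
            "[%s] rarefaction depth capped at the smallest plot total (%d)",
            tr, depth))
    rich <- rarefiedRichness(xt, depth)
    utils::write.csv(rich, file.path(outDir, paste0(tr, "_richness.csv")),
                     row.names = FALSE)
    nPlotsPerBand <- min(table(cd$band))
    rule <- commonSpeciesThreshold(nPlotsPerBand, commonP)
    message(sprintf("[%s] common-species threshold: N >= %d (n = %d, P = %.2f)",
                    tr, threshold(rule), nPlotsPerBand, commonP))
    common <- filterCommonSpecies(xt, rule)
    message(sprintf("[%s] %d of %d species are common", tr, nrow(common),
                    nrow(xt)))
    scheme <- candidateGroupings(xt)

    sims <- list(); perms <- list(); decays <- list()
    for (idx in indices) {
        sims[[idx]] <- pairwiseSimilarity(xt, index = idx, rule = rule)
        utils::write.csv(
            data.frame(plot_id = rownames(similarityValues(sims[[idx]])),
                       similarityValues(sims[[idx]]), check.names = FALSE),
            file.path(outDir, paste0(tr, "_similarity_", idx, ".csv")),
            row.names = FALSE)
        dis <- suppressWarnings(asDissimilarity(sims[[idx]]))
        pm <- permanova(dis, cd$band, nPermutations = nPermutations,
                        seed = seed + match(idx, indices))
        pm@pairwise <- pairwisePermanova(dis, cd$band,
                                         nPermutations = nPermutations,
                                         seed = seed + 100L + match(idx, indices))
        perms[[idx]] <- pm
        message(sprintf("[%s] PERMANOVA (%s): pseudo-F = %.3f, p = %.4g",
                        tr, idx, pseudoF(pm), pValue(pm)))
        if (idx != "raup_crick") {
            decays[[idx]] <- distanceDecayFit(sims[[idx]], xt)
            message(sprintf("[%s] decay (%s): slope = %.3g/m, R^2 = %.3f",
                            tr, idx, decaySlope(decays[[idx]]),
                            decays[[idx]]@rSquared))
        }
    }
    jsonlite::write_json(
        list(permanova = lapply(perms, .permanovaAsList),
             decay = lapply(decays, .decayAsList)),
        file.path(outDir, paste0(tr, "_inference.json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)

    indres <- indicatorSignificance(common, scheme,
                                    nPermutations = indicatorPermutations,
                                    seed = seed + 17L, alpha = alpha)
    utils::write.csv(indres, file.path(outDir, paste0(tr, "_indicators.csv")),
                     row.names = FALSE)
    es <- effectSizeNullModel(common, scheme, nNull = nNull,
                              nPermutations = indicatorPermutations,
                              innerPermutations = innerPermutations,
                              seed = seed + 29L, alpha = alpha)
    message(sprintf("[%s] indicators: %d significant of %d common; ES = %.3f",
                    tr, observedCount(es), nrow(common), effectSize(es)))
    if (writeFigures)
        .writeFigures(sims, es, xt, tr, outDir)
    list(richness = rich, rule = rule, common = common, similarity = sims,
         permanova = perms, decay = decays, indicators = indres,
         effectSize = es)
}

.permanovaAsList <- function(p) {
    list(pseudo_F = p@pseudoF, df_among = p@dfAmong, df_within = p@dfWithin,
         p_value = p@pValue, n_permutations = p@nPermutations,
         pairwise = p@pairwise)
}

.decayAsList <- function(d) {
    list(slope = d@slope, intercept = d@intercept, r_squared = d@rSquared,
         n_pairs = d@nPairs)
}

.pipelineSummary <- function(results, seed) {
    trs <- names(results)
    slope <- vapply(trs, function(tr) {
        d <- results[[tr]]$decay[["sorensen"]]
        if (is.null(d)) NA_real_ else d@slope
    }, numeric(1L))
    es <- vapply(trs, function(tr) effectSize(results[[tr]]$effectSize),
                 numeric(1L))
    list(seed = seed,
         transects = lapply(stats::setNames(trs, trs), function(tr) list(
             n_plots = nrow(results[[tr]]$richness),
             n_common_species = nrow(results[[tr]]$common),
             sorensen_decay_slope = slope[[tr]],
             observed_indicators = observedCount(results[[tr]]$effectSize),
             effect_size = es[[tr]])),
         ranking_by_decay_slope = trs[order(abs(slope), decreasing = TRUE)],
         ranking_by_effect_size = trs[order(es, decreasing = TRUE)])
}

.writeFigures <- function(sims, es, xt, tr, outDir) {
    if (!capabilities("cairo")) {
        message("cairo unavailable; skipping SVG figures")
        return(invisible(NULL))
    }
    s <- sims[["sorensen"]]
    if (!is.null(s)) {
        elev <- stats::setNames(colData(xt)$elevation_m, plotIDs(xt))
        v <- similarityValues(s)
        ut <- upper.tri(v)
        dEl <- abs(outer(elev[rownames(v)], elev[rownames(v)], "-"))[ut]
        grDevices::svg(file.path(outDir, paste0(tr, "_decay.svg")), 5, 4)
        graphics::plot(dEl, v[ut], xlab = "Delta elevation (m)",
                       ylab = "Sorensen similarity", pch = 19,
                       col = "#00000080", main = tr)
        graphics::abline(stats::lm(v[ut] ~ dEl), col = "firebrick")
        grDevices::dev.off()
    }
    grDevices::svg(file.path(outDir, paste0(tr, "_effect_size.svg")), 4, 4)
    graphics::boxplot(es@nullCounts, ylim = range(c(es@nullCounts,
                                                    es@observedCount)),
                      ylab = "significant indicator species", main = tr)
    graphics::points(1, es@observedCount, pch = 19, col = "firebrick")
    grDevices::dev.off()
    invisible(NULL)
}

#' NMDS ordination hook
#'
#' Visualization convenience only: delegates non-metric multidimensional
#' scaling to `vegan::metaMDS` (suggested package) on `1 - similarity` and
#' plots the configuration coloured by band. Stress minimization is not part
#' of this package's scope.
#'
#' @param sim a [SimilarityMatrix-class].
#' @param bands band label per plot (in plot order of `sim`).
#' @param ... passed to `vegan::metaMDS`.
#' @return the `metaMDS` object, invisibly.
#' @export
plotOrdination <- function(sim, bands, ...) {
    if (!requireNamespace("vegan", quietly = TRUE))
        stop("plotOrdination requires the suggested package 'vegan'")
    d <- suppressWarnings(asDissimilarity(sim))
    ord <- vegan::metaMDS(d, trace = 0, ...)
    pts <- vegan::scores(ord)
    graphics::plot(pts[, 1L], pts[, 2L], col = factor(bands), pch = 19,
                   xlab = "NMDS1", ylab = "NMDS2")
    graphics::legend("topright", legend = unique(bands),
                     col = factor(unique(bands)), pch = 19, bty = "n")
    invisible(ord)
}
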