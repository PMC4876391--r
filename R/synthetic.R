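#' Configure a synthetic elevational assemblage
#'
#' Defaults emulate a single light-trapping transect of the canonical design:
#' four elevational bands 200 m apart with five plots each, a species pool in
#' the low thousands with a long-tailed (log-normal) abundance distribution in
#' which roughly three quarters of species are rare (< 10 individuals),
#' Gaussian elevational niches of width 200 m, and overdispersed
#' (negative-binomial, k = 1) detection as typical for light-trap catches.
#' Plot elevations are jittered uniformly within +/- 20 m of their band.
#'
#' @param nSpecies species pool size (default 1500).
#' @param bandElevations band elevations in metres (default 800-1400 m).
#' @param plotsPerBand replicate plots per band (default 5).
#' @param nicheWidthSigma Gaussian niche SD in metres (default 200).
#' @param nicheCenterSpread metres beyond the gradient ends over which niche
#'   optima are drawn uniformly, so edge bands are not artificially
#'   depauperate (default 200).
#' @param sadMeanlog,sadSdlog log-normal parameters of species' peak expected
#'   abundances (defaults -2.25 and 2).
#' @param detection `"nbinom"` (default) or `"poisson"`.
#' @param dispersionK negative-binomial size parameter (default 1).
#' @param elevationJitter half-width of the uniform plot-elevation jitter in
#'   metres (default 20).
#' @param seed integer RNG seed (default 1).
#' @return a validated [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nSpecies = 1500,
                            bandElevations = c(800, 1000, 1200, 1400),
                            plotsPerBand = 5,
                            nicheWidthSigma = 200,
                            nicheCenterSpread = 200,
                            sadMeanlog = -2.25,
                            sadSdlog = 2,
                            detection = c("nbinom", "poisson"),
                            dispersionK = 1,
                            elevationJitter = 20,
                            seed = 1) {
    cfg <- new("SyntheticConfig",
               nSpecies = as.integer(nSpecies),
               bandElevations = as.numeric(bandElevations),
               plotsPerBand = as.integer(plotsPerBand),
               nicheWidthSigma = as.numeric(nicheWidthSigma),
               nicheCenterSpread = as.numeric(nicheCenterSpread),
               sadMeanlog = as.numeric(sadMeanlog),
               sadSdlog = as.numeric(sadSdlog),
               detection = match.arg(detection),
               dispersionK = as.numeric(dispersionK),
               elevationJitter = as.numeric(elevationJitter),
               seed = as.integer(seed))
    validObject(cfg)
    cfg
}

#' Generate one synthetic transect
#'
#' Species niches are Gaussian response curves along elevation: the expected
#' count of species \eqn{s} at plot \eqn{p} is
#' \deqn{\mu_{sp} = peak_s \exp\left(-\frac{(e_p - o_s)^2}{2\sigma^2}\right)}
#' with optima \eqn{o_s} uniform over the gradient extended by
#' `nicheCenterSpread` on both ends, peaks log-normal, and realized counts
#' drawn per (species, plot) from the detection distribution. The generating
#' truth (per-species optimum, width, peak; per-plot realized elevation) is
#' stored in `rowData`, `colData` and `metadata(x)$truth` for
#' parameter-recovery tests. Fully reproducible from `config@seed`.
#'
#' @param config a [SyntheticConfig-class].
#' @param transect transect label (default `"T1"`).
#' @param speciesPrefix prefix for species identifiers; keep prefixes distinct
#'   across transects so species namespaces are disjoint.
#' @return a [CommunityExperiment-class] with band/elevation metadata attached.
#' @export
generateAssemblage <- function(config, transect = "T1",
                               speciesPrefix = paste0(transect, "_sp")) {
    validObject(config)
    set.seed(config@seed)
    bands <- config@bandElevations
    P <- length(bands) * config@plotsPerBand
    S <- config@nSpecies
    lo <- min(bands) - config@nicheCenterSpread
    hi <- max(bands) + config@nicheCenterSpread
    optima <- stats::runif(S, lo, hi)
    peaks <- stats::rlnorm(S, config@sadMeanlog, config@sadSdlog)
    bandPer <- rep(bands, each = config@plotsPerBand)
    elev <- bandPer + stats::runif(P, -config@elevationJitter,
                                   config@elevationJitter)
    mu <- peaks * exp(-outer(optima, elev, "-")^2 /
                      (2 * config@nicheWidthSigma^2))
    n <- length(mu)
    cnt <- if (config@detection == "poisson") stats::rpois(n, mu)
           else stats::rnbinom(n, size = config@dispersionK, mu = mu)
    m <- matrix(as.numeric(cnt), S, P)
    fmt <- paste0("%0", nchar(S), "d")
    rownames(m) <- paste0(speciesPrefix, sprintf(fmt, seq_len(S)))
    plotIds <- paste0(transect, "_", rep(format(bands, trim = TRUE),
                                         each = config@plotsPerBand),
                      "_p", rep(seq_len(config@plotsPerBand),
                                times = length(bands)))
    colnames(m) <- plotIds
    cd <- DataFrame(transect = rep(transect, P),
                    band = rep(format(bands, trim = TRUE),
                               each = config@plotsPerBand),
                    elevation_m = elev,
                    row.names = plotIds)
    x <- CommunityExperiment(m, plotData = cd)
    rowData(x) <- DataFrame(niche_optimum_m = optima,
                            niche_width_m = rep(config@nicheWidthSigma, S),
                            peak_abundance = peaks)
    metadata(x)$truth <- list(niche_optimum_m = optima,
                              niche_width_m = rep(config@nicheWidthSigma, S),
                              peak_abundance = peaks,
                              plot_elevation_m = stats::setNames(elev, plotIds))
    metadata(x)$config <- config
    x
}

#' Generate a multi-transect dataset
#'
#' Combines several independently generated transects into one community with
#' disjoint species namespaces, emulating a multi-bioregion design in which
#' (almost) no species is shared between transects. Requires at least two
#' configurations.
#'
#' @param configs list of [SyntheticConfig-class] objects (length >= 2).
#' @param transectNames labels, default `"T1"`, `"T2"`, ...
#' @return a pooled [CommunityExperiment-class]; species occurring on one
#'   transect have all-zero counts on the others.
#' @export
generateMultiTransect <- function(configs, transectNames = NULL) {
    if (!is.list(configs) || length(configs) < 2L)
        stop("at least two transect configurations are required")
    if (is.null(transectNames))
        transectNames <- paste0("T", seq_along(configs))
    if (anyDuplicated(transectNames))
        stop("transect names must be distinct")
    parts <- mapply(function(cfg, tr) generateAssemblage(cfg, transect = tr),
                    configs, transectNames, SIMPLIFY = FALSE)
    allPlots <- unlist(lapply(parts, plotIDs))
    if (anyDuplicated(allPlots))
        stop("overlapping plot identifiers across transects")
    allSpecies <- unlist(lapply(parts, speciesIDs))
    if (anyDuplicated(allSpecies))
        stop("species namespaces overlap across transects")
    m <- matrix(0, length(allSpecies), length(allPlots),
                dimnames = list(allSpecies, allPlots))
    cds <- list()
    for (p in parts) {
        m[speciesIDs(p), plotIDs(p)] <- counts(p)
        cds[[length(cds) + 1L]] <- colData(p)
    }
    cd <- do.call(rbind, cds)
    x <- CommunityExperiment(m, plotData = cd)
    metadata(x)$truth <- lapply(parts, function(p) metadata(p)$truth)
    names(metadata(x)$truth) <- transectNames
    x
}
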