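# Programmatic fixtures shared across test files.

# A CommunityExperiment from a plots-by-species count matrix plus band labels.
makeCE <- function(counts, bands = NULL, elevations = NULL, transect = "T1",
                   plotIds = NULL, speciesIds = NULL) {
    counts <- as.matrix(counts)
    if (is.null(plotIds)) plotIds <- paste0("p", seq_len(nrow(counts)))
    if (is.null(speciesIds)) speciesIds <- paste0("sp", seq_len(ncol(counts)))
    dimnames(counts) <- list(plotIds, speciesIds)
    cd <- S4Vectors::DataFrame(row.names = plotIds)
    if (!is.null(bands)) {
        cd$transect <- rep(transect, nrow(counts))
        cd$band <- as.character(bands)
        cd$elevation_m <- if (is.null(elevations))
            as.numeric(as.character(bands)) else elevations
    }
    CommunityExperiment(counts, plotData = cd, speciesAsRows = FALSE)
}

# Canonical 4-band x 5-plot toy design (20 plots) with given per-plot species
# abundances supplied as a plots-by-species matrix.
bandDesign20 <- function() {
    list(bands = rep(c("800", "1000", "1200", "1400"), each = 5),
         elevations = rep(c(800, 1000, 1200, 1400), each = 5))
}
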