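#' Construct a CommunityExperiment
#'
#' @param counts numeric matrix of non-negative integer abundances with
#'   species as rows and plots as columns (dimnames required). A plots-by-
#'   species matrix can be passed with `speciesAsRows = FALSE`.
#' @param plotData optional `DataFrame`/`data.frame` of plot metadata, one row
#'   per plot, with rownames (or a `plot_id` column) matching the plot ids.
#'   Recognised columns: `transect`, `band`, `elevation_m`, `stratum`, `site`.
#' @param speciesAsRows logical; set `FALSE` if `counts` has plots as rows.
#'
#' @return A [CommunityExperiment-class] object.
#' @examples
#' m <- matrix(c(1L, 0L, 0L, 2L), 2, dimnames = list(c("sp1", "sp2"),
#'                                                   c("p1", "p2")))
#' ce <- CommunityExperiment(m)
#' plotTotals(ce)
#' @export
CommunityExperiment <- function(counts, plotData = NULL, speciesAsRows = TRUE) {
    counts <- as.matrix(counts)
    if (!speciesAsRows)
        counts <- t(counts)
    storage.mode(counts) <- "double"
    if (ncol(counts) < 1L)
        stop("at least one plot is required")
    if (nrow(counts) < 1L)
        stop("at least one species column is required")
    if (is.null(plotData)) {
        plotData <- DataFrame(row.names = colnames(counts))
    } else {
        plotData <- as(plotData, "DataFrame")
        if ("plot_id" %in% names(plotData) && is.null(rownames(plotData)))
            rownames(plotData) <- plotData$plot_id
        plotData <- .alignPlotData(plotData, colnames(counts))
    }
    se <- SummarizedExperiment(assays = list(counts = counts),
                               colData = plotData)
    new("CommunityExperiment", se)
}

.alignPlotData <- function(plotData, plotIds) {
    missing <- setdiff(plotIds, rownames(plotData))
    if (length(missing))
        stop("no metadata record for plot(s): ",
             paste(missing, collapse = ", "))
    plotData[plotIds, , drop = FALSE]
}

#' @describeIn CommunityExperiment-class abundance matrix (species x plots).
#' @param object,x a `CommunityExperiment`.
#' @export
setMethod("counts", "CommunityExperiment",
          function(object) assay(object, "counts"))

#' @export
setGeneric("plotIDs", function(x) standardGeneric("plotIDs"))
#' @describeIn CommunityExperiment-class plot identifiers.
#' @export
setMethod("plotIDs", "CommunityExperiment", function(x) colnames(x))

#' @export
setGeneric("speciesIDs", function(x) standardGeneric("speciesIDs"))
#' @describeIn CommunityExperiment-class species identifiers.
#' @export
setMethod("speciesIDs", "CommunityExperiment", function(x) rownames(x))

#' @export
setGeneric("plotTotals", function(x) standardGeneric("plotTotals"))
#' @describeIn CommunityExperiment-class total individuals per plot.
#' @export
setMethod("plotTotals", "CommunityExperiment",
          function(x) colSums(counts(x)))

#' @export
setGeneric("speciesTotals", function(x) standardGeneric("speciesTotals"))
#' @describeIn CommunityExperiment-class total individuals per species.
#' @export
setMethod("speciesTotals", "CommunityExperiment",
          function(x) rowSums(counts(x)))

#' @export
setGeneric("transects", function(x) standardGeneric("transects"))
#' @describeIn CommunityExperiment-class unique transect labels (or `NA` when
#'   no transect metadata is attached).
#' @export
setMethod("transects", "CommunityExperiment", function(x) {
    cd <- colData(x)
    if (!"transect" %in% names(cd)) return(NA_character_)
    unique(cd$transect)
})

#' @export
setGeneric("bandsOrdered", function(x) standardGeneric("bandsOrdered"))
#' @describeIn CommunityExperiment-class band labels ordered by mean elevation
#'   (never lexicographically).
#' @export
setMethod("bandsOrdered", "CommunityExperiment", function(x) {
    cd <- colData(x)
    if (!all(c("band", "elevation_m") %in% names(cd)))
        stop("plot metadata with 'band' and 'elevation_m' is required")
    mean_elev <- tapply(cd$elevation_m, cd$band, mean)
    names(sort(mean_elev))
})

setMethod("show", "CommunityExperiment", function(object) {
    cat(sprintf("CommunityExperiment: %d species x %d plots, %d individuals\n",
                nrow(object), ncol(object), sum(counts(object))))
    cd <- colData(object)
    if ("transect" %in% names(cd))
        cat("  transects: ", paste(unique(cd$transect), collapse = ", "), "\n",
            sep = "")
    if (all(c("band", "elevation_m") %in% names(cd)))
        cat("  bands: ", paste(bandsOrdered(object), collapse = " < "), "\n",
            sep = "")
})

#' Restrict a community to one transect
#'
#' @param x a [CommunityExperiment-class] with `transect` metadata.
#' @param transect transect label.
#' @param dropEmptySpecies drop species with zero total in the transect
#'   (default `TRUE`, so the species pool is the set recorded on the transect).
#' @return a `CommunityExperiment` containing only the transect's plots.
#' @export
subsetTransect <- function(x, transect, dropEmptySpecies = TRUE) {
    cd <- colData(x)
    if (!"transect" %in% names(cd))
        stop("no transect metadata attached")
    keep <- cd$transect == transect
    if (!any(keep))
        stop("unknown transect: ", transect)
    out <- x[, keep]
    if (dropEmptySpecies)
        out <- out[rowSums(counts(out)) > 0, ]
    out
}
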