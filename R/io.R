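#' Read a plot-by-species abundance CSV
#'
#' The expected layout has a header row of species identifiers and plot
#' identifiers in the first column (one row per plot), comma-separated, UTF-8.
#' Files with species as rows and plots as columns are read with
#' `speciesAsRows = TRUE`. Cells must be non-negative integers; input ordering
#' of plots and species is preserved.
#'
#' @param path path to the CSV file.
#' @param speciesAsRows set `TRUE` for transposed files (species in the first
#'   column, plots in the header).
#' @return a [CommunityExperiment-class] without plot metadata (see
#'   [readMetadataCSV()] and [attachPlotData()]).
#' @export
readCommunityCSV <- function(path, speciesAsRows = FALSE) {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
    if (ncol(df) < 2L)
        stop("no species columns found in ", path)
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
        stop("duplicate ", if (speciesAsRows) "species" else "plot",
             " identifiers: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    colIds <- names(df)[-1L]  # data.frame subsetting would uniquify these
    if (anyDuplicated(colIds))
        stop("duplicate ", if (speciesAsRows) "plot" else "species",
             " identifiers: ",
             paste(unique(colIds[duplicated(colIds)]), collapse = ", "))
    raw <- as.matrix(df[, -1L, drop = FALSE])
    colnames(raw) <- colIds
    m <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw),
                                 dimnames = dimnames(raw)))
    bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf(
            "non-integer or negative count at row '%s', column '%s' in %s",
            ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]], path))
    rownames(m) <- ids
    CommunityExperiment(m, speciesAsRows = speciesAsRows)
}

#' Write a CommunityExperiment to CSV
#'
#' Inverse of [readCommunityCSV()]: plots as rows, species as columns, counts
#' written as integers so that a write/read round trip reproduces the matrix
#' exactly.
#'
#' @param x a [CommunityExperiment-class].
#' @param path output path.
#' @param speciesAsRows write the transposed (species-per-row) layout.
#' @return `path`, invisibly.
#' @export
writeCommunityCSV <- function(x, path, speciesAsRows = FALSE) {
    m <- counts(x)
    storage.mode(m) <- "integer"
    if (!speciesAsRows)
        m <- t(m)
    df <- data.frame(id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1L] <- if (speciesAsRows) "species_id" else "plot_id"
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    invisible(path)
}

#' Read plot metadata from CSV
#'
#' Required columns: `plot_id`, `transect`, `band`, `elevation_m`. Optional:
#' `stratum` (canopy / ground) and `site` (the physical plot shared by
#' strata, used by [poolStrata()]).
#'
#' @param path path to the CSV file.
#' @return a `DataFrame` keyed by `plot_id` with bands orderable by mean
#'   elevation.
#' @export
readMetadataCSV <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
    req <- c("plot_id", "transect", "band", "elevation_m")
    miss <- setdiff(req, names(df))
    if (length(miss))
        stop("metadata file lacks required column(s): ",
             paste(miss, collapse = ", "))
    if (anyDuplicated(df$plot_id))
        stop("plot(s) listed twice in metadata: ",
             paste(unique(df$plot_id[duplicated(df$plot_id)]), collapse = ", "))
    if (!is.numeric(df$elevation_m))
        stop("elevation_m must be numeric")
    df$plot_id <- as.character(df$plot_id)
    df$transect <- as.character(df$transect)
    df$band <- as.character(df$band)
    out <- as(df, "DataFrame")
    rownames(out) <- out$plot_id
    out
}

#' Attach plot metadata to a community
#'
#' Joins a metadata table onto the plots of a [CommunityExperiment-class].
#' Every plot must have exactly one metadata record; metadata rows for plots
#' absent from the matrix are dropped, and bands left with zero plots after
#' the join are dropped with a warning.
#'
#' @param x a `CommunityExperiment`.
#' @param plotData metadata as returned by [readMetadataCSV()].
#' @return `x` with populated `colData`.
#' @export
attachPlotData <- function(x, plotData) {
    plotData <- as(plotData, "DataFrame")
    if ("plot_id" %in% names(plotData))
        rownames(plotData) <- plotData$plot_id
    aligned <- .alignPlotData(plotData, plotIDs(x))
    lost <- setdiff(unique(plotData$band), unique(aligned$band))
    if (length(lost))
        warning("band(s) with no plots in the community matrix dropped: ",
                paste(lost, collapse = ", "))
    colData(x) <- aligned
    validObject(x)
    x
}

#' Pool canopy and understorey samples per plot
#'
#' Samples sharing a (transect, site) key but differing in `stratum` are summed
#' per species into a single plot whose id is the site label. Plots without a
#' stratum record pass through unchanged. Total abundance per species and per
#' site is conserved.
#'
#' @param x a [CommunityExperiment-class] whose metadata may contain `stratum`
#'   and `site` columns.
#' @return a `CommunityExperiment` with one column per plot site; the pooled
#'   metadata keeps transect/band (which must agree within a site) and the
#'   mean elevation, and drops the stratum column.
#' @export
poolStrata <- function(x) {
    cd <- colData(x)
    if (!"stratum" %in% names(cd) || all(is.na(cd$stratum)))
        return(x)
    if (!"site" %in% names(cd))
        stop("pooling strata requires a 'site' metadata column")
    key <- ifelse(is.na(cd$stratum), plotIDs(x),
                  paste(cd$transect, cd$site, sep = "\r"))
    m <- counts(x)
    groups <- split(seq_len(ncol(m)), factor(key, levels = unique(key)))
    pooled <- vapply(groups, function(j) rowSums(m[, j, drop = FALSE]),
                     numeric(nrow(m)))
    newIds <- vapply(groups, function(j) {
        s <- cd$site[j[1L]]
        if (is.na(cd$stratum[j[1L]]) || is.null(s) || is.na(s))
            plotIDs(x)[j[1L]] else as.character(s)
    }, character(1L))
    if (anyDuplicated(newIds))
        stop("pooled plot identifiers collide: ",
             paste(unique(newIds[duplicated(newIds)]), collapse = ", "))
    colnames(pooled) <- newIds
    newCd <- DataFrame(row.names = newIds)
    for (col in c("transect", "band")) {
        if (!col %in% names(cd)) next
        vals <- vapply(groups, function(j) {
            u <- unique(cd[[col]][j])
            if (length(u) > 1L)
                stop("plots pooled into one site disagree on '", col, "'")
            u
        }, character(1L))
        newCd[[col]] <- vals
    }
    if ("elevation_m" %in% names(cd))
        newCd$elevation_m <- vapply(groups,
                                    function(j) mean(cd$elevation_m[j]),
                                    numeric(1L))
    CommunityExperiment(pooled, plotData = newCd)
}
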