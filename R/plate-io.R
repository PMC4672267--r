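# Plate-map CSV and JSON config I/O.
#
# Plate maps are CSVs with header well_id,positive,colony_count and 96-well
# style coordinates ("A01"). Serialization is canonical: rows are written in
# row-major well order (row letter, then column number), so
# write -> read -> write is a fixpoint.

#' Generate well ids in row-major plate order
#'
#' Ids follow the 96-well convention (letter row + zero-padded column,
#' "A01" ... "H12"). Designs larger than one plate (e.g. the 160-well
#' campaign spread over two 96-well plates) continue the row letters past
#' "H", i.e. a flattened multi-plate layout.
#'
#' (rows past "Z" get double letters, spreadsheet style).
#'
#' @param n number of wells.
#' @param nCols columns per plate row (default 12).
#' @return character vector of n well ids in row-major order.
#' @examples
#' makeWellIds(80)[c(1, 80)]  # "A01" "G08"
#' @export
makeWellIds <- function(n, nCols = 12L) {
    n <- as.integer(n)
    stopifnot(n >= 1L)
    i <- seq_len(n) - 1L
    sprintf("%s%02d", rowLabel(i %/% nCols + 1L), i %% nCols + 1L)
}

# spreadsheet-style row labels: A..Z, AA..AZ, ...
rowLabel <- function(k) {
    vapply(k, function(x) {
        s <- ""
        while (x > 0L) {
            s <- paste0(LETTERS[(x - 1L) %% 26L + 1L], s)
            x <- (x - 1L) %/% 26L
        }
        s
    }, character(1))
}

wellOrder <- function(ids) {
    rows <- sub("[0-9]+$", "", ids)
    cols <- as.integer(sub("^[A-Z]+", "", ids))
    order(nchar(rows), rows, cols)
}

#' Read a plate map CSV into an ExperimentRecord
#'
#' Expects a CSV with header \code{well_id,positive,colony_count}. Each row
#' must satisfy the digital-readout invariant: \code{positive} is true
#' exactly when \code{colony_count >= 1}.
#'
#' @param path CSV file path.
#' @param experimentId label for the record; defaults to the file name
#'   without extension.
#' @param design optional \code{AssayDesign} to attach (validated against
#'   the number of wells).
#' @return an \code{ExperimentRecord} with wells in row-major order.
#' @seealso [writePlateMap()]
#' @export
readPlateMap <- function(path, experimentId = NULL, design = NULL) {
    if (is.null(experimentId))
        experimentId <- sub("\\.[^.]*$", "", basename(path))
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("well_id", "positive", "colony_count")
    if (!all(need %in% names(df)))
        stop("plate map ", path, " must have columns ",
             paste(need, collapse = ", "))
    if (anyDuplicated(df$well_id))
        stop("duplicate well id(s) in ", path, ": ",
             paste(unique(df$well_id[duplicated(df$well_id)]),
                   collapse = ", "))
    pos <- parseBool(df$positive)
    cnt <- as.integer(df$colony_count)
    bad <- which(pos != (cnt >= 1L))
    if (length(bad))
        stop("inconsistent positive/colony_count for well(s): ",
             paste(df$well_id[bad], collapse = ", "))
    df <- df[wellOrder(df$well_id), , drop = FALSE]
    wells <- mapply(WellCall, wellId = df$well_id,
                    colonyCount = as.integer(df$colony_count),
                    SIMPLIFY = FALSE, USE.NAMES = FALSE)
    ExperimentRecord(experimentId = experimentId, wells = wells,
                     design = design)
}

parseBool <- function(x) {
    if (is.logical(x)) return(x)
    out <- tolower(as.character(x)) %in% c("true", "t", "1", "yes")
    ok <- tolower(as.character(x)) %in%
        c("true", "t", "1", "yes", "false", "f", "0", "no")
    if (!all(ok)) stop("unparseable positive value(s): ",
                       paste(unique(x[!ok]), collapse = ", "))
    out
}

#' Write an ExperimentRecord as a plate map CSV
#'
#' Wells are serialized in canonical row-major order regardless of their
#' order in the record, so output is byte-stable.
#'
#' @param record a valid \code{ExperimentRecord}.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @seealso [readPlateMap()]
#' @export
writePlateMap <- function(record, path) {
    validObject(record)
    df <- data.frame(well_id = wellIds(record),
                     positive = tolower(as.character(isPositive(record))),
                     colony_count = unname(colonyCounts(record)),
                     stringsAsFactors = FALSE)
    df <- df[wellOrder(df$well_id), , drop = FALSE]
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

# JSON configs use snake_case keys mirroring the assay nomenclature.
designFieldMap <- c(
    total_carrier_cells = "totalCarrierCells",
    spike_cells = "spikeCells",
    n_wells = "nWells",
    carrier_cells_per_well = "carrierCellsPerWell",
    n_experiments = "nExperiments",
    mean_spike_per_well = "meanSpikePerWell")

criteriaFieldMap <- c(
    min_area = "minArea",
    min_circularity = "minCircularity",
    min_mean_intensity = "minMeanIntensity",
    segmentation_threshold = "segmentationThreshold",
    threshold_method = "thresholdMethod",
    smoothing_sigma = "smoothingSigma",
    pre_sieve_fraction = "preSieveFraction",
    overlap_fraction = "overlapFraction",
    brightfield_contrast = "brightfieldContrast",
    pixel_scale = "pixelScale")

fromJSONConfig <- function(path, map, constructor) {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(cfg), names(map))
    if (length(unknown))
        stop("unknown config field(s) in ", path, ": ",
             paste(unknown, collapse = ", "))
    args <- stats::setNames(cfg, map[names(cfg)])
    do.call(constructor, args)
}

toJSONConfig <- function(object, map, path) {
    vals <- lapply(map, function(s) slot(object, s))
    vals <- vals[!vapply(vals, function(v) length(v) == 1L && is.na(v),
                         logical(1))]
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' Read or write assay-design / detection-criteria JSON configs
#'
#' Config files use snake_case keys (\code{n_wells}, \code{min_area}, ...)
#' matching the slot names of the corresponding classes; \code{NA} slots are
#' omitted on write.
#'
#' @param path JSON file path.
#' @return the parsed \code{AssayDesign} / \code{DetectionCriteria}.
#' @export
readAssayDesign <- function(path)
    fromJSONConfig(path, designFieldMap, AssayDesign)

#' @rdname readAssayDesign
#' @export
readDetectionCriteria <- function(path)
    fromJSONConfig(path, criteriaFieldMap, DetectionCriteria)

#' @rdname readAssayDesign
#' @param object an \code{AssayDesign} or \code{DetectionCriteria}.
#' @export
writeAssayDesign <- function(object, path)
    toJSONConfig(object, designFieldMap, path)

#' @rdname readAssayDesign
#' @export
writeDetectionCriteria <- function(object, path)
    toJSONConfig(object, criteriaFieldMap, path)
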