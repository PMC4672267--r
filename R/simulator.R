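# Monte-Carlo simulation of digital SACF campaigns: spiking, partitioning
# into wells, stochastic colony formation, and (optionally) rendering each
# well through the imaging pipeline and reading it back with detectWell.

#' Randomly partition a fixed spike of cells across wells
#'
#' Multinomial placement with equal well probabilities — the partition
#' model for a well-mixed cell suspension aliquoted evenly, under which
#' per-well occupancy is Binomial(n, 1/W), i.e. Poisson-like for large W.
#' Counts always sum to \code{nCells} exactly.
#'
#' @param nCells cells to place.
#' @param nWells number of wells, >= 1.
#' @param seed integer seed, or \code{NULL} to draw from the current RNG
#'   stream.
#' @return integer vector of per-well counts.
#' @examples
#' sum(simulatePartition(40, 80, seed = 1))  # 40
#' @export
simulatePartition <- function(nCells, nWells, seed = NULL) {
    stopifnot(nWells >= 1, nCells >= 0)
    if (!is.null(seed)) set.seed(seed)
    if (nCells == 0) return(integer(nWells))
    as.integer(stats::rmultinom(1, nCells, rep(1 / nWells, nWells)))
}

#' Simulate stochastic colony formation in dispensed wells
#'
#' Each dispensed cell independently forms a colony with probability
#' \code{efficiency} (per-cell Bernoulli model); the per-well colony count
#' is the number of successes, never exceeding the cell count.
#'
#' @param perWellCells integer vector of dispensed cells per well.
#' @param efficiency per-cell colony-forming probability, in [0, 1].
#' @param seed integer seed, or \code{NULL}.
#' @param experimentId label for the resulting record.
#' @return an \code{ExperimentRecord} with one \code{WellCall} per well.
#' @export
simulateColonyFormation <- function(perWellCells, efficiency, seed = NULL,
                                    experimentId = "sim") {
    stopifnot(efficiency >= 0, efficiency <= 1)
    if (!is.null(seed)) set.seed(seed)
    counts <- as.integer(stats::rbinom(length(perWellCells), perWellCells,
                                       efficiency))
    ids <- makeWellIds(length(perWellCells))
    # counts are valid by construction; skip the per-well constructor
    wells <- lapply(seq_along(counts), function(i)
        new("WellCall", wellId = ids[i], positive = counts[i] >= 1L,
            colonyCount = counts[i], candidates = list()))
    ExperimentRecord(experimentId = experimentId, wells = wells)
}

defaultRenderOptions <- function(opts = list()) {
    base <- list(shape = c(512L, 512L), noiseSd = 5, backgroundLevel = 10,
                 colonyRadius = 60, colonyPeak = 200,
                 criteria = DetectionCriteria())
    base[names(opts)] <- opts
    base
}

# place n colony centres with a margin and pairwise separation so rendered
# blobs stay inside the raster and do not merge
placeColonies <- function(n, shape, radius) {
    if (n == 0L) return(data.frame(row = numeric(), col = numeric(),
                                   radius = numeric()))
    margin <- ceiling(1.6 * radius)
    rows <- numeric(0); cols <- numeric(0)
    for (i in seq_len(n)) {
        for (try in 1:200) {
            r <- stats::runif(1, margin, shape[1] - margin)
            cc <- stats::runif(1, margin, shape[2] - margin)
            if (!length(rows) ||
                all((rows - r)^2 + (cols - cc)^2 > (2.5 * radius)^2)) {
                rows <- c(rows, r); cols <- c(cols, cc)
                break
            }
        }
        if (length(rows) < i)
            stop("could not place ", n, " colonies in a ",
                 shape[1], "x", shape[2], " raster without overlap")
    }
    data.frame(row = rows, col = cols, radius = radius)
}

#' Simulate a full digital SACF campaign
#'
#' Runs \code{nReplicates} independent campaigns of the configured design.
#' Each experiment partitions the spike (multinomially for fixed-spike
#' designs, Poisson per well for mean-dispensed designs), forms colonies
#' per cell with the configured efficiency, and optionally flips
#' colony-free wells positive at \code{falsePositiveRatePerWell}. With
#' \code{renderImages = TRUE}, every well is rendered as a synthetic image
#' and the call is read back through \code{\link{detectWell}} (closed
#' loop). Per-experiment seeds are derived deterministically from the
#' master seed, so any replicate can be reproduced in isolation. For large
#' power runs set \code{keepRecords = FALSE} to skip materializing
#' per-well records and return only the detection frequency and histogram
#' (identical values, same RNG stream).
#'
#' @param config a \code{SimulationConfig}.
#' @return a \code{SimulationResult}: per-replicate records, the fraction
#'   of experiments with at least one positive well, and the relative
#'   frequency of positive-well counts per experiment.
#' @examples
#' cfg <- SimulationConfig(AssayDesign(spikeCells = 1, nWells = 80),
#'                         efficiency = 0.688, nReplicates = 200, seed = 7)
#' detectionFrequency(simulateCampaign(cfg))  # ~0.688
#' @export
simulateCampaign <- function(config) {
    validObject(config)
    design <- config@design
    nExp <- design@nExperiments
    total <- config@nReplicates * nExp
    set.seed(config@seed)
    expSeeds <- sample.int(.Machine$integer.max - 1L, total)
    ropts <- defaultRenderOptions(config@renderOptions)

    keep <- config@keepRecords || config@renderImages
    ids <- makeWellIds(design@nWells)
    perReplicate <- if (keep) vector("list", config@nReplicates)
                    else list()
    positives <- integer(total)
    k <- 0L
    for (rep in seq_len(config@nReplicates)) {
        recs <- if (keep) vector("list", nExp)
        for (e in seq_len(nExp)) {
            k <- k + 1L
            set.seed(expSeeds[k])
            cells <- if (!is.na(design@spikeCells))
                simulatePartition(design@spikeCells, design@nWells)
            else
                stats::rpois(design@nWells, design@meanSpikePerWell)
            counts <- as.integer(stats::rbinom(design@nWells, cells,
                                               config@efficiency))
            if (config@falsePositiveRatePerWell > 0) {
                flip <- stats::runif(design@nWells) <
                    config@falsePositiveRatePerWell
                counts[flip & counts == 0L] <- 1L
            }
            if (keep) {
                wells <- lapply(seq_along(counts), function(i)
                    new("WellCall", wellId = ids[i],
                        positive = counts[i] >= 1L,
                        colonyCount = counts[i], candidates = list()))
                rec <- ExperimentRecord(
                    experimentId = sprintf("rep%d_exp%d", rep, e),
                    wells = wells)
                if (config@renderImages)
                    rec <- renderAndDetect(rec, ropts)
                recs[[e]] <- rec
                positives[k] <- nPositive(rec)
            } else {
                positives[k] <- sum(counts >= 1L)
            }
        }
        if (keep) perReplicate[[rep]] <- recs
    }
    hist <- table(positives) / total
    new("SimulationResult", perReplicate = perReplicate,
        detectionFrequency = mean(positives >= 1L),
        positiveWellHistogram = stats::setNames(as.numeric(hist),
                                                names(hist)))
}

# closed loop: materialize each well of a record as a synthetic image and
# re-derive the calls with detectWell
renderAndDetect <- function(rec, ropts) {
    wells <- lapply(rec@wells, function(w) {
        truth <- GroundTruth(colonies = placeColonies(
            w@colonyCount, ropts$shape, ropts$colonyRadius))
        img <- generateWellImage(truth, shape = ropts$shape,
            noiseSd = ropts$noiseSd,
            backgroundLevel = ropts$backgroundLevel,
            seed = sample.int(.Machine$integer.max - 1L, 1),
            colonyPeak = ropts$colonyPeak, wellId = w@wellId)
        if (!is.null(ropts$outDir)) writeWellImage(img, ropts$outDir)
        detectWell(img, ropts$criteria)
    })
    ExperimentRecord(experimentId = rec@experimentId, wells = wells)
}

#' Serialize a SimulationResult to JSON
#'
#' Writes the detection frequency, the positive-well histogram and the
#' per-experiment positive-well counts; output is byte-stable for a given
#' configuration and seed.
#'
#' @param result a \code{SimulationResult}.
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
writeSimulationResult <- function(result, path) {
    perExp <- lapply(result@perReplicate, function(recs)
        vapply(recs, nPositive, integer(1)))
    jsonlite::write_json(list(
        detection_frequency = result@detectionFrequency,
        positive_well_histogram = as.list(result@positiveWellHistogram),
        positive_wells_per_experiment = perExp
    ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}
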