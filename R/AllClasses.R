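#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Partitioned assay design
#'
#' Describes how a cell preparation is partitioned across wells in a digital
#' soft agar colony formation (SACF) campaign: the carrier-cell load, the
#' (known or intended) transformed-cell spike, the number of wells per
#' experiment and the number of replicate experiments.
#'
#' Two spike parameterizations are supported: a fixed spike of
#' \code{spikeCells} transformed cells randomly partitioned across the wells
#' (the single-spiked-cell campaigns), or Poisson dispensing at
#' \code{meanSpikePerWell} cells per well (the efficiency-measurement design
#' at 0.5 cells/well). At least one of the two must be given.
#'
#' @slot totalCarrierCells total carrier (e.g. hMSC) cells across the
#'   experiment, or \code{NA}.
#' @slot spikeCells number of transformed cells spiked into the preparation,
#'   or \code{NA}.
#' @slot nWells number of wells (partitions) per experiment.
#' @slot carrierCellsPerWell carrier cells dispensed per well, or \code{NA}.
#' @slot nExperiments number of replicate experiments in the campaign.
#' @slot meanSpikePerWell mean transformed cells dispensed per well for
#'   Poisson-dispensed designs, or \code{NA}.
#' @export
setClass("AssayDesign",
    representation(
        totalCarrierCells = "numeric",
        spikeCells = "numeric",
        nWells = "integer",
        carrierCellsPerWell = "numeric",
        nExperiments = "integer",
        meanSpikePerWell = "numeric"
    ),
    prototype(
        totalCarrierCells = NA_real_,
        spikeCells = NA_real_,
        nWells = 80L,
        carrierCellsPerWell = NA_real_,
        nExperiments = 1L,
        meanSpikePerWell = NA_real_
    )
)

setValidity("AssayDesign", function(object) {
    msg <- character()
    if (length(object@nWells) != 1L || is.na(object@nWells) ||
        object@nWells < 1L)
        msg <- c(msg, "nWells must be a single integer >= 1")
    if (!is.na(object@nExperiments) && object@nExperiments < 1L)
        msg <- c(msg, "nExperiments must be >= 1")
    for (s in c("totalCarrierCells", "spikeCells", "carrierCellsPerWell",
                "meanSpikePerWell")) {
        v <- slot(object, s)
        if (!is.na(v) && v < 0)
            msg <- c(msg, sprintf("%s must be >= 0", s))
    }
    if (is.na(object@spikeCells) && is.na(object@meanSpikePerWell))
        msg <- c(msg,
            "one of spikeCells or meanSpikePerWell must be given")
    if (!is.na(object@carrierCellsPerWell) &&
        !is.na(object@totalCarrierCells) &&
        object@carrierCellsPerWell * object@nWells !=
            object@totalCarrierCells)
        msg <- c(msg,
            "carrierCellsPerWell * nWells must equal totalCarrierCells")
    if (length(msg)) msg else TRUE
})

#' @rdname AssayDesign-class
#' @param totalCarrierCells,spikeCells,nWells,carrierCellsPerWell
#'   see slot descriptions.
#' @param nExperiments,meanSpikePerWell see slot descriptions.
#' @return an \code{AssayDesign} object.
#' @examples
#' # the 0.0001% campaign: 1 HeLa cell in 1e6 hMSCs over 80 wells, 5 runs
#' AssayDesign(totalCarrierCells = 1e6, spikeCells = 1, nWells = 80,
#'             carrierCellsPerWell = 12500, nExperiments = 5)
#' @export
AssayDesign <- function(totalCarrierCells = NA_real_, spikeCells = NA_real_,
                        nWells = 80L, carrierCellsPerWell = NA_real_,
                        nExperiments = 1L, meanSpikePerWell = NA_real_) {
    new("AssayDesign",
        totalCarrierCells = as.numeric(totalCarrierCells),
        spikeCells = as.numeric(spikeCells),
        nWells = as.integer(nWells),
        carrierCellsPerWell = as.numeric(carrierCellsPerWell),
        nExperiments = as.integer(nExperiments),
        meanSpikePerWell = as.numeric(meanSpikePerWell))
}

#' Colony detection criteria
#'
#' Thresholds applied when segmenting per-channel fluorescence images and
#' sieving candidate regions into confirmed colonies. The defaults are the
#' screening criteria used for colonies sedimented from dissolved soft agar:
#' area > 6000 (squared pixels by default; see \code{pixelScale}),
#' circularity > 0.4, mean fluorescence intensity > 100 on the image's
#' native scale. All three filters use strict inequalities.
#'
#' @slot minArea minimum region area (exclusive), default 6000.
#' @slot minCircularity minimum form factor 4*pi*A/P^2 (exclusive), in
#'   [0, 1], default 0.4.
#' @slot minMeanIntensity minimum mean raw intensity inside the region
#'   (exclusive), default 100.
#' @slot segmentationThreshold per-channel intensity cut for rough
#'   segmentation (pixels >= threshold are foreground), default 100.
#' @slot thresholdMethod \code{"fixed"} (use segmentationThreshold) or
#'   \code{"otsu"} (data-driven threshold per channel).
#' @slot smoothingSigma SD (pixels) of the Gaussian pre-smoothing applied
#'   before thresholding so that pixel noise does not shred region
#'   boundaries; 0 disables smoothing. Default 2. Intensity features are
#'   always measured on the raw raster.
#' @slot preSieveFraction components smaller than this fraction of
#'   \code{minArea} are discarded before feature computation, default 0.01.
#' @slot overlapFraction minimum (overlap area)/(smaller region area) for a
#'   red/blue match, in (0, 1], default 0.5.
#' @slot brightfieldContrast minimum absolute contrast (mean in-footprint
#'   minus image median) required on the bright-field channel to confirm a
#'   colony; \code{NA} (default) disables the bright-field check.
#' @slot pixelScale physical length per pixel, or \code{NA}; when set,
#'   \code{minArea} is interpreted in squared physical units.
#' @export
setClass("DetectionCriteria",
    representation(
        minArea = "numeric",
        minCircularity = "numeric",
        minMeanIntensity = "numeric",
        segmentationThreshold = "numeric",
        thresholdMethod = "character",
        smoothingSigma = "numeric",
        preSieveFraction = "numeric",
        overlapFraction = "numeric",
        brightfieldContrast = "numeric",
        pixelScale = "numeric"
    ),
    prototype(
        minArea = 6000,
        minCircularity = 0.4,
        minMeanIntensity = 100,
        segmentationThreshold = 100,
        thresholdMethod = "fixed",
        smoothingSigma = 2,
        preSieveFraction = 0.01,
        overlapFraction = 0.5,
        brightfieldContrast = NA_real_,
        pixelScale = NA_real_
    )
)

setValidity("DetectionCriteria", function(object) {
    msg <- character()
    if (object@minArea <= 0)
        msg <- c(msg, "minArea must be > 0")
    if (object@minCircularity < 0 || object@minCircularity > 1)
        msg <- c(msg, "minCircularity must be in [0, 1]")
    if (object@overlapFraction <= 0 || object@overlapFraction > 1)
        msg <- c(msg, "overlapFraction must be in (0, 1]")
    if (!object@thresholdMethod %in% c("fixed", "otsu"))
        msg <- c(msg, "thresholdMethod must be 'fixed' or 'otsu'")
    if (object@preSieveFraction < 0)
        msg <- c(msg, "preSieveFraction must be >= 0")
    if (object@smoothingSigma < 0)
        msg <- c(msg, "smoothingSigma must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @rdname DetectionCriteria-class
#' @param minArea,minCircularity,minMeanIntensity,segmentationThreshold
#'   see slot descriptions.
#' @param thresholdMethod,preSieveFraction,overlapFraction see slots.
#' @param brightfieldContrast,pixelScale see slot descriptions.
#' @return a \code{DetectionCriteria} object.
#' @examples
#' DetectionCriteria()  # screening defaults: >6000 / >0.4 / >100
#' @export
DetectionCriteria <- function(minArea = 6000, minCircularity = 0.4,
                              minMeanIntensity = 100,
                              segmentationThreshold = 100,
                              thresholdMethod = c("fixed", "otsu"),
                              smoothingSigma = 2,
                              preSieveFraction = 0.01,
                              overlapFraction = 0.5,
                              brightfieldContrast = NA_real_,
                              pixelScale = NA_real_) {
    new("DetectionCriteria",
        minArea = as.numeric(minArea),
        minCircularity = as.numeric(minCircularity),
        minMeanIntensity = as.numeric(minMeanIntensity),
        segmentationThreshold = as.numeric(segmentationThreshold),
        thresholdMethod = match.arg(thresholdMethod),
        smoothingSigma = as.numeric(smoothingSigma),
        preSieveFraction = as.numeric(preSieveFraction),
        overlapFraction = as.numeric(overlapFraction),
        brightfieldContrast = as.numeric(brightfieldContrast),
        pixelScale = as.numeric(pixelScale))
}

#' Segmented candidate region
#'
#' One connected component recovered from a single fluorescence channel,
#' with the measured features used by the sieve filter. Circularity is the
#' form factor 4*pi*area/perimeter^2, clamped to [0, 1]; the perimeter is a
#' corrected digital contour length so a rasterized disk scores ~1.
#'
#' @slot channel channel name ("red" or "blue").
#' @slot label integer component id, assigned in scanline order.
#' @slot area region size (pixels, or squared physical units when a
#'   pixelScale is configured).
#' @slot perimeter boundary length in the same length unit.
#' @slot circularity form factor in [0, 1].
#' @slot meanIntensity mean raw intensity inside the region.
#' @slot centroid numeric (row, col) centroid.
#' @slot pixels integer vector of linear (column-major) pixel indices.
#' @slot dim integer (nrow, ncol) of the source raster.
#' @export
setClass("RegionCandidate",
    representation(
        channel = "character",
        label = "integer",
        area = "numeric",
        perimeter = "numeric",
        circularity = "numeric",
        meanIntensity = "numeric",
        centroid = "numeric",
        pixels = "integer",
        dim = "integer"
    )
)

setValidity("RegionCandidate", function(object) {
    msg <- character()
    if (object@area <= 0) msg <- c(msg, "area must be > 0")
    if (object@circularity < 0 || object@circularity > 1)
        msg <- c(msg, "circularity must be in [0, 1]")
    if (object@meanIntensity < 0)
        msg <- c(msg, "meanIntensity must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Digital readout of one well
#'
#' A well is "positive" exactly when at least one confirmed dual-channel
#' colony was found in it; \code{colonyCount} counts confirmed colonies
#' (not raw candidates, which are retained in \code{candidates} for audit).
#'
#' @slot wellId plate coordinate such as "A01".
#' @slot positive logical colony-formation call.
#' @slot colonyCount number of confirmed dual-channel colonies.
#' @slot candidates list of \code{RegionCandidate} retained after filtering.
#' @export
setClass("WellCall",
    representation(
        wellId = "character",
        positive = "logical",
        colonyCount = "integer",
        candidates = "list"
    ),
    prototype(candidates = list())
)

#' @rdname WellCall-class
#' @param wellId,positive,colonyCount,candidates see slot descriptions.
#' @return a \code{WellCall} object.
#' @export
WellCall <- function(wellId, colonyCount = 0L,
                     positive = colonyCount >= 1L, candidates = list()) {
    wellId <- as.character(wellId)
    positive <- as.logical(positive)
    colonyCount <- as.integer(colonyCount)
    if (length(wellId) != 1L || !grepl("^[A-Z]+[0-9]{2,}$", wellId))
        stop("wellId must look like 'A01'")
    if (is.na(colonyCount) || colonyCount < 0L)
        stop("colonyCount must be a non-negative integer")
    if (positive != (colonyCount >= 1L))
        stop(sprintf(
            "well %s: positive must hold exactly when colonyCount >= 1",
            wellId))
    new("WellCall", wellId = wellId, positive = positive,
        colonyCount = colonyCount, candidates = candidates)
}

#' One plate-replicate's digital readout
#'
#' The full set of per-well calls for one experiment (one pass of the
#' partitioned assay), optionally tied to the \code{AssayDesign} that
#' produced it (in which case the number of wells must match the design).
#'
#' @slot experimentId experiment label.
#' @slot wells list of \code{WellCall}, unique well ids.
#' @slot design the \code{AssayDesign}, or \code{NULL}.
#' @export
setClass("ExperimentRecord",
    representation(
        experimentId = "character",
        wells = "list",
        design = "ANY"
    ),
    prototype(experimentId = "exp1", wells = list(), design = NULL)
)

setValidity("ExperimentRecord", function(object) {
    msg <- character()
    if (!all(vapply(object@wells, is, logical(1), "WellCall")))
        msg <- c(msg, "wells must all be WellCall objects")
    else {
        ids <- vapply(object@wells, slot, character(1), "wellId")
        if (anyDuplicated(ids))
            msg <- c(msg, sprintf("duplicate well id(s): %s",
                paste(unique(ids[duplicated(ids)]), collapse = ", ")))
        bad <- vapply(object@wells, function(w)
            w@positive != (w@colonyCount >= 1L), logical(1))
        if (any(bad))
            msg <- c(msg, sprintf(
                "positive flag inconsistent with colonyCount for: %s",
                paste(ids[bad], collapse = ", ")))
    }
    if (!is.null(object@design)) {
        if (!is(object@design, "AssayDesign"))
            msg <- c(msg, "design must be an AssayDesign or NULL")
        else if (length(object@wells) != object@design@nWells)
            msg <- c(msg, sprintf(
                "record has %d wells but design expects %d",
                length(object@wells), object@design@nWells))
    }
    if (length(msg)) msg else TRUE
})

#' @rdname ExperimentRecord-class
#' @param experimentId,wells,design see slot descriptions.
#' @return an \code{ExperimentRecord} object.
#' @export
ExperimentRecord <- function(experimentId = "exp1", wells = list(),
                             design = NULL) {
    new("ExperimentRecord", experimentId = as.character(experimentId),
        wells = wells, design = design)
}

#' Multi-channel image of one well
#'
#' The raster data for one well: red and blue fluorescence plus
#' bright-field, each either a single stitched raster or a list of four
#' field-of-view tiles in fixed 2x2 row-major order (stitched on demand by
#' \code{\link{detectWell}}).
#'
#' @slot wellId plate coordinate.
#' @slot channels named list with entries \code{red}, \code{blue},
#'   \code{brightfield}; each a matrix or a list of 4 equally-shaped
#'   matrices.
#' @slot fieldsPerWell 1 or 4.
#' @slot intensityScale maximum representable intensity (e.g. 255).
#' @export
setClass("WellImage",
    representation(
        wellId = "character",
        channels = "list",
        fieldsPerWell = "integer",
        intensityScale = "numeric"
    ),
    prototype(fieldsPerWell = 1L, intensityScale = 255)
)

setValidity("WellImage", function(object) {
    msg <- character()
    need <- c("red", "blue", "brightfield")
    if (!all(need %in% names(object@channels)))
        msg <- c(msg, sprintf("missing channel(s): %s",
            paste(setdiff(need, names(object@channels)), collapse = ", ")))
    if (!object@fieldsPerWell %in% c(1L, 4L))
        msg <- c(msg, "fieldsPerWell must be 1 or 4")
    dims <- lapply(object@channels, function(ch) {
        if (is.list(ch)) dim(ch[[1]]) else dim(ch)
    })
    if (length(dims) > 1L &&
        !all(vapply(dims, identical, logical(1), dims[[1]])))
        msg <- c(msg, "all channel rasters must share identical dimensions")
    rng <- range(unlist(lapply(object@channels, function(ch)
        if (is.list(ch)) range(vapply(ch, range, numeric(2)))
        else range(ch))))
    if (rng[1] < 0 || rng[2] > object@intensityScale)
        msg <- c(msg, "intensities must lie in [0, intensityScale]")
    if (length(msg)) msg else TRUE
})

#' @rdname WellImage-class
#' @param wellId,channels,fieldsPerWell,intensityScale see slots.
#' @return a \code{WellImage} object.
#' @export
WellImage <- function(wellId, channels, fieldsPerWell = 1L,
                      intensityScale = 255) {
    new("WellImage", wellId = as.character(wellId), channels = channels,
        fieldsPerWell = as.integer(fieldsPerWell),
        intensityScale = as.numeric(intensityScale))
}

#' Planted ground truth for a synthetic well
#'
#' Describes the objects planted in a synthetic well image: true colonies
#' (bright, roughly circular, present in both fluorescence channels by
#' construction) and debris objects planted as false-positive bait. Debris
#' kinds: \code{"mono-red"} / \code{"mono-blue"} (single-channel disks,
#' excluded by the dual-channel rule), \code{"bar"} (elongated dual-channel
#' objects, excluded by circularity), \code{"speck"} (dual-channel specks
#' below the area criterion).
#'
#' @slot colonies data.frame with columns row, col, radius (pixels).
#' @slot debris data.frame with columns row, col, kind, size.
#' @export
setClass("GroundTruth",
    representation(colonies = "data.frame", debris = "data.frame"),
    prototype(
        colonies = data.frame(row = numeric(), col = numeric(),
                              radius = numeric()),
        debris = data.frame(row = numeric(), col = numeric(),
                            kind = character(), size = numeric()))
)

setValidity("GroundTruth", function(object) {
    msg <- character()
    if (!all(c("row", "col", "radius") %in% names(object@colonies)))
        msg <- c(msg, "colonies needs columns row, col, radius")
    else if (nrow(object@colonies) && any(object@colonies$radius <= 0))
        msg <- c(msg, "colony radii must be > 0")
    if (!all(c("row", "col", "kind", "size") %in% names(object@debris)))
        msg <- c(msg, "debris needs columns row, col, kind, size")
    else if (nrow(object@debris) &&
             !all(object@debris$kind %in%
                  c("mono-red", "mono-blue", "bar", "speck")))
        msg <- c(msg, "debris kind must be mono-red/mono-blue/bar/speck")
    if (length(msg)) msg else TRUE
})

#' @rdname GroundTruth-class
#' @param colonies,debris see slot descriptions.
#' @return a \code{GroundTruth} object.
#' @examples
#' GroundTruth(colonies = data.frame(row = 256, col = 256, radius = 60))
#' @export
GroundTruth <- function(colonies = NULL, debris = NULL) {
    proto <- new("GroundTruth")
    if (!is.null(colonies)) proto@colonies <- colonies
    if (!is.null(debris)) proto@debris <- debris
    validObject(proto)
    proto
}

#' Pooled per-well colony rate
#'
#' @slot pNegative probability a well shows no colony.
#' @slot pPositive 1 - pNegative.
#' @slot nWellsObserved pooled number of wells.
#' @slot nPositiveObserved pooled number of positive wells.
#' @export
setClass("WellRateEstimate",
    representation(pNegative = "numeric", pPositive = "numeric",
                   nWellsObserved = "integer", nPositiveObserved = "integer")
)

#' Replicate plan bounding the campaign false-negative rate
#'
#' @slot x false-negative rate of one experiment (per-well negative rate
#'   raised to the number of wells).
#' @slot yTarget permissible campaign false-negative rate.
#' @slot nExact log(yTarget)/log(x).
#' @slot nRequired ceiling(nExact); x^nRequired <= yTarget.
#' @export
setClass("FalseNegativePlan",
    representation(x = "numeric", yTarget = "numeric", nExact = "numeric",
                   nRequired = "integer")
)

#' Colony-forming efficiency estimate
#'
#' @slot efficiency pooled colonies/dispensed ratio.
#' @slot coloniesTotal total colonies across experiments.
#' @slot cellsDispensed total (estimated) transformed cells dispensed.
#' @slot perExperiment data.frame with columns colonies, dispensed, ratio.
#' @slot meanRatio,sdRatio mean and SD of the per-experiment ratios.
#' @export
setClass("EfficiencyEstimate",
    representation(efficiency = "numeric", coloniesTotal = "numeric",
                   cellsDispensed = "numeric", perExperiment = "data.frame",
                   meanRatio = "numeric", sdRatio = "numeric")
)

#' Impurity load estimate
#'
#' @slot estimateCells estimated transformed cells in the preparation.
#' @slot method "colony-ratio" or "mpn".
#' @slot assumedEfficiency colony-forming efficiency assumed for the
#'   impurity (taken from the positive-control cells).
#' @slot confidenceInterval (lower, upper) bootstrap interval, or NAs.
#' @slot level confidence level of the interval.
#' @export
setClass("ImpurityEstimate",
    representation(estimateCells = "numeric", method = "character",
                   assumedEfficiency = "numeric",
                   confidenceInterval = "numeric", level = "numeric")
)

#' Simulation configuration
#'
#' @slot design the \code{AssayDesign} simulated.
#' @slot efficiency per-cell colony-forming probability in [0, 1].
#' @slot nReplicates number of simulated campaigns.
#' @slot seed master seed; per-replicate seeds are derived from it.
#' @slot renderImages render each well through the imaging pipeline and
#'   read the calls back with \code{detectWell} (closed loop).
#' @slot falsePositiveRatePerWell probability a colony-free well is still
#'   called positive, default 0.
#' @slot keepRecords store the per-well \code{ExperimentRecord}s of every
#'   replicate (default TRUE); disable for large power runs where only the
#'   detection frequency and histogram are needed.
#' @slot renderOptions list of rendering parameters (shape, backgroundLevel,
#'   noiseSd, colonyRadius, colonyPeak) used when renderImages is TRUE.
#' @export
setClass("SimulationConfig",
    representation(design = "AssayDesign", efficiency = "numeric",
                   nReplicates = "integer", seed = "integer",
                   renderImages = "logical",
                   falsePositiveRatePerWell = "numeric",
                   keepRecords = "logical",
                   renderOptions = "list"),
    prototype(nReplicates = 1L, seed = 1L, renderImages = FALSE,
              falsePositiveRatePerWell = 0, keepRecords = TRUE,
              renderOptions = list())
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@efficiency < 0 || object@efficiency > 1)
        msg <- c(msg, "efficiency must be in [0, 1]")
    if (object@nReplicates < 1L)
        msg <- c(msg, "nReplicates must be >= 1")
    if (object@falsePositiveRatePerWell < 0 ||
        object@falsePositiveRatePerWell >= 1)
        msg <- c(msg, "falsePositiveRatePerWell must be in [0, 1)")
    if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#' @param design,efficiency,nReplicates,seed,renderImages see slots.
#' @param falsePositiveRatePerWell,renderOptions see slot descriptions.
#' @return a \code{SimulationConfig} object.
#' @export
SimulationConfig <- function(design, efficiency, nReplicates = 1L,
                             seed = 1L, renderImages = FALSE,
                             falsePositiveRatePerWell = 0,
                             keepRecords = TRUE, renderOptions = list()) {
    new("SimulationConfig", design = design,
        efficiency = as.numeric(efficiency),
        nReplicates = as.integer(nReplicates), seed = as.integer(seed),
        renderImages = as.logical(renderImages),
        falsePositiveRatePerWell = as.numeric(falsePositiveRatePerWell),
        keepRecords = as.logical(keepRecords),
        renderOptions = renderOptions)
}

#' Simulated campaign result
#'
#' @slot perReplicate list (one element per replicate) of lists of
#'   \code{ExperimentRecord}.
#' @slot detectionFrequency fraction of simulated experiments with at least
#'   one positive well.
#' @slot positiveWellHistogram named numeric: relative frequency of each
#'   positive-well count per experiment (frequencies sum to 1).
#' @export
setClass("SimulationResult",
    representation(perReplicate = "list", detectionFrequency = "numeric",
                   positiveWellHistogram = "numeric")
)
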