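#' @rdname ExperimentRecord-class
#' @param record an \code{ExperimentRecord}.
#' @export
wellIds <- function(record) {
    vapply(record@wells, slot, character(1), "wellId")
}

#' @rdname ExperimentRecord-class
#' @export
colonyCounts <- function(record) {
    stats::setNames(vapply(record@wells, slot, integer(1), "colonyCount"),
                    wellIds(record))
}

#' @rdname ExperimentRecord-class
#' @export
isPositive <- function(record) {
    stats::setNames(vapply(record@wells, slot, logical(1), "positive"),
                    wellIds(record))
}

#' @rdname ExperimentRecord-class
#' @export
nPositive <- function(record) sum(isPositive(record))

#' @rdname WellRateEstimate-class
#' @param object the estimate.
#' @export
pNegative <- function(object) object@pNegative

#' @rdname WellRateEstimate-class
#' @export
pPositive <- function(object) object@pPositive

#' @rdname FalseNegativePlan-class
#' @param plan a \code{FalseNegativePlan}.
#' @export
nRequired <- function(plan) plan@nRequired

#' @rdname FalseNegativePlan-class
#' @export
nExact <- function(plan) plan@nExact

#' @rdname EfficiencyEstimate-class
#' @param object the estimate.
#' @export
efficiency <- function(object) object@efficiency

#' @rdname ImpurityEstimate-class
#' @param object the estimate.
#' @export
estimateCells <- function(object) object@estimateCells

#' @rdname SimulationResult-class
#' @param object the result.
#' @export
detectionFrequency <- function(object) object@detectionFrequency

setMethod("show", "AssayDesign", function(object) {
    cat("AssayDesign:", object@nWells, "wells x", object@nExperiments,
        "experiment(s)\n")
    if (!is.na(object@spikeCells))
        cat("  fixed spike:", object@spikeCells, "transformed cell(s)\n")
    if (!is.na(object@meanSpikePerWell))
        cat("  Poisson dispensing:", object@meanSpikePerWell,
            "cells/well\n")
    if (!is.na(object@carrierCellsPerWell))
        cat("  carrier cells/well:", object@carrierCellsPerWell, "\n")
})

setMethod("show", "DetectionCriteria", function(object) {
    cat("DetectionCriteria: area >", object@minArea,
        "& circularity >", object@minCircularity,
        "& mean intensity >", object@minMeanIntensity, "\n")
    cat("  segmentation: ", object@thresholdMethod, " threshold ",
        object@segmentationThreshold, ", overlap fraction ",
        object@overlapFraction, "\n", sep = "")
})

setMethod("show", "WellCall", function(object) {
    cat(sprintf("WellCall %s: %s (%d colon%s)\n", object@wellId,
        if (object@positive) "positive" else "negative",
        object@colonyCount, if (object@colonyCount == 1L) "y" else "ies"))
})

setMethod("show", "ExperimentRecord", function(object) {
    cat(sprintf("ExperimentRecord '%s': %d wells, %d positive\n",
        object@experimentId, length(object@wells), nPositive(object)))
})

setMethod("show", "WellImage", function(object) {
    d <- dim(if (is.list(object@channels[[1]])) object@channels[[1]][[1]]
             else object@channels[[1]])
    cat(sprintf("WellImage %s: %s, %d field(s)/well, %dx%d\n",
        object@wellId, paste(names(object@channels), collapse = "/"),
        object@fieldsPerWell, d[1], d[2]))
})

setMethod("show", "WellRateEstimate", function(object) {
    cat(sprintf(
        "WellRateEstimate: p(negative) = %.4g, p(positive) = %.4g (%d/%d wells positive)\n",
        object@pNegative, object@pPositive, object@nPositiveObserved,
        object@nWellsObserved))
})

setMethod("show", "FalseNegativePlan", function(object) {
    cat(sprintf(
        "FalseNegativePlan: x = %.4g, target y = %.3g -> n = %.4g, %d experiment(s) required\n",
        object@x, object@yTarget, object@nExact, object@nRequired))
})

setMethod("show", "EfficiencyEstimate", function(object) {
    cat(sprintf(
        "EfficiencyEstimate: %.3g (%g colonies / %g cells dispensed); per-experiment %.3g +/- %.3g\n",
        object@efficiency, object@coloniesTotal, object@cellsDispensed,
        object@meanRatio, object@sdRatio))
})

setMethod("show", "ImpurityEstimate", function(object) {
    cat(sprintf("ImpurityEstimate (%s): %.4g cells at assumed efficiency %.3g\n",
        object@method, object@estimateCells, object@assumedEfficiency))
    if (!anyNA(object@confidenceInterval))
        cat(sprintf("  %g%% bootstrap CI: [%.4g, %.4g]\n",
            100 * object@level, object@confidenceInterval[1],
            object@confidenceInterval[2]))
})

setMethod("show", "SimulationResult", function(object) {
    cat(sprintf(
        "SimulationResult: %d replicate(s), detection frequency %.4g\n",
        length(object@perReplicate), object@detectionFrequency))
})
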