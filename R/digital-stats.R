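# Digital (partitioned) assay statistics: per-well rates, false-negative
# arithmetic, replicate planning, LLOD, colony-forming efficiency and
# impurity estimation.
#
# The digital readout treats each well as a binary partition. With per-well
# negative rate q over W wells, one experiment misses a contaminated
# preparation with probability x = q^W, and n replicate experiments with
# y = x^n; n = log(y)/log(x) experiments bound the campaign false-negative
# rate at y.

#' Pooled per-well colony rate from replicate experiments
#'
#' Pools positive-well counts across experiments: p(positive) = total
#' positive wells / total wells (integer counts are pooled first and
#' divided once, so printed rates like 397/400 = 0.9925 are reproduced
#' exactly). Per-experiment averaging is available as an option.
#'
#' @param records list of \code{ExperimentRecord} sharing a well count.
#' @param pooled pool counts across experiments (default) or average the
#'   per-experiment positive fractions.
#' @return a \code{WellRateEstimate}.
#' @examples
#' # five 80-well experiments, one positive well in three of them
#' recs <- lapply(1:5, function(i) {
#'   counts <- integer(80); if (i <= 3) counts[1] <- 1L
#'   ExperimentRecord(paste0("exp", i),
#'     mapply(WellCall, makeWellIds(80), counts, SIMPLIFY = FALSE))
#' })
#' estimateWellRate(recs)  # p(negative) 0.9925
#' @export
estimateWellRate <- function(records, pooled = TRUE) {
    if (!length(records)) stop("at least one ExperimentRecord is required")
    nw <- vapply(records, function(r) length(r@wells), integer(1))
    if (any(nw == 0L)) stop("records must contain at least one well")
    if (length(unique(nw)) != 1L)
        stop("all records must share the same number of wells")
    pos <- vapply(records, nPositive, integer(1))
    if (pooled) {
        pPos <- sum(pos) / sum(nw)
    } else {
        pPos <- mean(pos / nw)
    }
    new("WellRateEstimate", pNegative = 1 - pPos, pPositive = pPos,
        nWellsObserved = sum(nw), nPositiveObserved = sum(pos))
}

#' False-negative rate of one partitioned experiment
#'
#' With per-well negative rate \code{pNegative} over \code{nWells}
#' independent wells, one experiment detects nothing with probability
#' \code{pNegative^nWells}.
#'
#' @param pNegative per-well probability of no colony, in [0, 1].
#' @param nWells wells per experiment, >= 1.
#' @return the experiment false-negative rate.
#' @examples
#' experimentFalseNegative(0.9925, 80)   # 0.5476
#' experimentFalseNegative(0.9956, 160)  # 0.4938
#' @export
experimentFalseNegative <- function(pNegative, nWells) {
    stopifnot(pNegative >= 0, pNegative <= 1, nWells >= 1)
    pNegative^nWells
}

#' Number of replicate experiments bounding the false-negative rate
#'
#' Solves y = x^n for the number n of replicate experiments needed so the
#' campaign false-negative rate does not exceed \code{yTarget}:
#' n = log(yTarget)/log(x), rounded up.
#'
#' @param x false-negative rate of one experiment, in (0, 1).
#' @param yTarget permissible campaign false-negative rate, in (0, 1).
#' @return a \code{FalseNegativePlan}; \code{nRequired(plan)} experiments
#'   guarantee x^n <= yTarget.
#' @examples
#' requiredExperiments(0.5476, 0.01)  # 8 experiments
#' requiredExperiments(0.4938, 0.01)  # 7 experiments
#' @export
requiredExperiments <- function(x, yTarget = 0.01) {
    if (x >= 1)
        stop("cannot bound the false-negative rate: ",
             "single-experiment rate x must be < 1")
    stopifnot(x > 0, yTarget > 0, yTarget < 1)
    nEx <- log(yTarget) / log(x)
    new("FalseNegativePlan", x = x, yTarget = yTarget, nExact = nEx,
        nRequired = as.integer(ceiling(nEx)))
}

#' Lower limit of detection from negative-control measurements
#'
#' Background mean plus \code{k} times the standard deviation of the
#' negative-control measurements (k = 3.3 by convention). Sample SD
#' (denominator n-1) is the default; set \code{sample = FALSE} for the
#' population SD.
#'
#' @param backgroundValues numeric vector of >= 2 control measurements.
#' @param k SD multiplier (default 3.3).
#' @param sample use the n-1 denominator (default TRUE).
#' @return the detection limit on the scale of the measurements.
#' @examples
#' llod(c(0, 2))  # 1 + 3.3 * sqrt(2)
#' @export
llod <- function(backgroundValues, k = 3.3, sample = TRUE) {
    if (length(backgroundValues) < 2L)
        stop("at least two background measurements are required")
    s <- stats::sd(backgroundValues)
    if (!sample) {
        n <- length(backgroundValues)
        s <- s * sqrt((n - 1) / n)
    }
    mean(backgroundValues) + k * s
}

#' Estimate the number of cells dispensed into an assay
#'
#' From manual counts on a counting (Terasaki) plate: the concentration is
#' the summed count divided by the total counted volume, scaled to the
#' volume dispensed into the assay. Volumes must share a unit.
#'
#' @param terasakiCounts per-well manual counts.
#' @param volumePerWell counted volume per well.
#' @param assayVolumeTotal total volume dispensed into the assay plate.
#' @return estimated number of dispensed cells.
#' @examples
#' # 40 cells over 40 x 10 uL -> 100 cells/mL; 0.4 mL dispensed -> 40 cells
#' estimateDispensedCells(rep(1, 40), 0.01, 0.4)
#' @export
estimateDispensedCells <- function(terasakiCounts, volumePerWell,
                                   assayVolumeTotal) {
    if (!length(terasakiCounts)) stop("no counts supplied")
    stopifnot(all(terasakiCounts >= 0), volumePerWell > 0,
              assayVolumeTotal > 0)
    conc <- sum(terasakiCounts) / (length(terasakiCounts) * volumePerWell)
    conc * assayVolumeTotal
}

#' Colony-forming efficiency from replicate experiments
#'
#' The ratio of total colonies to total transformed cells dispensed, pooled
#' across experiments; per-experiment ratios are also reported with their
#' mean and SD.
#'
#' @param records list of \code{ExperimentRecord}.
#' @param dispensedPerExperiment numeric vector, one (estimated) dispensed
#'   cell count per record.
#' @return an \code{EfficiencyEstimate}.
#' @export
estimateEfficiency <- function(records, dispensedPerExperiment) {
    if (length(records) != length(dispensedPerExperiment))
        stop("one dispensed-cell count is required per experiment record")
    if (any(dispensedPerExperiment <= 0))
        stop("dispensed cell counts must be > 0")
    colonies <- vapply(records, function(r) sum(colonyCounts(r)),
                       numeric(1))
    ratio <- colonies / dispensedPerExperiment
    eff <- sum(colonies) / sum(dispensedPerExperiment)
    if (eff > 1)
        warning("estimated efficiency exceeds 1; check colony counts ",
                "and dispensed-cell estimates")
    new("EfficiencyEstimate", efficiency = eff,
        coloniesTotal = sum(colonies),
        cellsDispensed = sum(dispensedPerExperiment),
        perExperiment = data.frame(colonies = colonies,
                                   dispensed = dispensedPerExperiment,
                                   ratio = ratio),
        meanRatio = mean(ratio),
        sdRatio = if (length(ratio) > 1L) stats::sd(ratio) else NA_real_)
}

#' Estimate the transformed-cell load of a preparation
#'
#' Converts a digital readout into an estimated number of transformed
#' cells, assuming the impurity shares the colony-forming efficiency of the
#' positive-control cells. Two estimators:
#' \describe{
#'   \item{colony-ratio}{total observed colonies / efficiency.}
#'   \item{mpn}{most probable number: per-well rate
#'     lambda = -log(fraction of negative wells) / efficiency, scaled by
#'     the number of wells; corrects for multiple colonies co-occupying a
#'     well being read as one positive partition.}
#' }
#'
#' @param records list of \code{ExperimentRecord} (pooled).
#' @param efficiency assumed colony-forming efficiency, in (0, 1].
#' @param method "colony-ratio" or "mpn".
#' @param ci compute a percentile bootstrap confidence interval
#'   (resampling wells with replacement).
#' @param level confidence level (default 0.95).
#' @param nBoot bootstrap draws (default 2000).
#' @param seed seed for the bootstrap.
#' @return an \code{ImpurityEstimate}.
#' @examples
#' # 3 positives in 400 wells at efficiency 0.688
#' recs <- lapply(1:5, function(i) {
#'   counts <- integer(80); if (i <= 3) counts[1] <- 1L
#'   ExperimentRecord(paste0("exp", i),
#'     mapply(WellCall, makeWellIds(80), counts, SIMPLIFY = FALSE))
#' })
#' estimateCells(estimateImpurity(recs, 0.688, "mpn"))  # ~4.38
#' @export
estimateImpurity <- function(records, efficiency,
                             method = c("colony-ratio", "mpn"),
                             ci = FALSE, level = 0.95, nBoot = 2000L,
                             seed = 1L) {
    method <- match.arg(method)
    stopifnot(efficiency > 0, efficiency <= 1)
    counts <- unlist(lapply(records, function(r)
        unname(colonyCounts(r))))
    nW <- length(counts)
    if (!nW) stop("no wells in the supplied records")
    pointEstimate <- function(cnt) {
        if (method == "colony-ratio") {
            sum(cnt) / efficiency
        } else {
            negFrac <- mean(cnt == 0L)
            if (negFrac == 0)
                stop("MPN estimate is unbounded when every well is ",
                     "positive; increase the partition number")
            -log(negFrac) / efficiency * length(cnt)
        }
    }
    est <- pointEstimate(counts)
    interval <- c(NA_real_, NA_real_)
    if (ci) {
        set.seed(seed)
        boot <- vapply(seq_len(nBoot), function(b) {
            res <- counts[sample.int(nW, nW, replace = TRUE)]
            if (method == "mpn" && !any(res == 0L)) return(NA_real_)
            pointEstimate(res)
        }, numeric(1))
        interval <- unname(stats::quantile(boot,
            c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE))
    }
    new("ImpurityEstimate", estimateCells = est, method = method,
        assumedEfficiency = efficiency, confidenceInterval = interval,
        level = level)
}

#' Probability that one experiment detects the spike
#'
#' Under independent per-cell colony formation with probability
#' \code{efficiency}: for a fixed spike of T cells randomly partitioned
#' across the wells, P(at least one positive well) = 1 - (1 - f)^T,
#' regardless of how the cells land. For Poisson-dispensed designs with
#' mean lambda cells/well, the returned value is the per-well positive
#' probability 1 - exp(-lambda * f); see
#' \code{\link{expectedPositiveWells}} for the experiment-level count.
#'
#' @param design an \code{AssayDesign}.
#' @param efficiency per-cell colony-forming probability, in [0, 1].
#' @return a probability.
#' @examples
#' d <- AssayDesign(spikeCells = 1, nWells = 80)
#' detectionProbability(d, 0.688)  # 0.688
#' @export
detectionProbability <- function(design, efficiency) {
    stopifnot(efficiency >= 0, efficiency <= 1)
    validObject(design)
    if (!is.na(design@spikeCells))
        1 - (1 - efficiency)^design@spikeCells
    else
        1 - exp(-design@meanSpikePerWell * efficiency)
}

#' Expected number of positive wells in one experiment
#'
#' For Poisson dispensing at mean lambda cells/well, each well is positive
#' with probability 1 - exp(-lambda * f), so the expectation is
#' nWells * (1 - exp(-lambda * f)). For a fixed spike of T cells the
#' expectation is nWells * (1 - (1 - f/nWells)^T).
#'
#' @inheritParams detectionProbability
#' @return expected positive wells.
#' @examples
#' d <- AssayDesign(meanSpikePerWell = 0.5, nWells = 80)
#' expectedPositiveWells(d, 0.447)  # ~16.03
#' @export
expectedPositiveWells <- function(design, efficiency) {
    stopifnot(efficiency >= 0, efficiency <= 1)
    validObject(design)
    W <- design@nWells
    if (!is.na(design@meanSpikePerWell))
        W * (1 - exp(-design@meanSpikePerWell * efficiency))
    else
        W * (1 - (1 - efficiency / W)^design@spikeCells)
}

#' Impurity concentration as a percentage
#'
#' @param spikeCells transformed cells present.
#' @param totalCells total cells in the preparation.
#' @return 100 * spikeCells / totalCells.
#' @examples
#' percentImpurity(1, 1e7)  # 1e-5 (%)
#' @export
percentImpurity <- function(spikeCells, totalCells) {
    stopifnot(totalCells > 0, spikeCells >= 0)
    100 * spikeCells / totalCells
}

#' Summarize a digital campaign
#'
#' Convenience wrapper producing the quantities a digital-assay report
#' needs: the pooled per-well rate, the single-experiment false-negative
#' rate, the replicate plan for a target campaign false-negative rate, and
#' (when an efficiency is supplied) the impurity estimate.
#'
#' @param records list of \code{ExperimentRecord}.
#' @param yTarget permissible campaign false-negative rate (default 0.01).
#' @param efficiency optional assumed colony-forming efficiency.
#' @param method impurity estimator, "mpn" or "colony-ratio".
#' @return a list with elements \code{wellRate}, \code{x}, \code{plan} and
#'   optionally \code{impurity}, suitable for JSON serialization via
#'   \code{\link{writeDigitalSummary}}.
#' @export
digitalSummary <- function(records, yTarget = 0.01, efficiency = NULL,
                           method = "mpn") {
    rate <- estimateWellRate(records)
    nW <- length(records[[1]]@wells)
    x <- experimentFalseNegative(rate@pNegative, nW)
    plan <- if (x < 1) requiredExperiments(x, yTarget) else NULL
    out <- list(wellRate = rate, x = x, plan = plan)
    if (!is.null(efficiency))
        out$impurity <- estimateImpurity(records, efficiency,
                                         method = method)
    out
}

#' @rdname digitalSummary
#' @param summary the list returned by \code{digitalSummary}.
#' @param path output JSON path.
#' @export
writeDigitalSummary <- function(summary, path) {
    x <- list(
        p_negative = summary$wellRate@pNegative,
        p_positive = summary$wellRate@pPositive,
        n_wells_observed = summary$wellRate@nWellsObserved,
        n_positive_observed = summary$wellRate@nPositiveObserved,
        experiment_false_negative = summary$x)
    if (!is.null(summary$plan))
        x <- c(x, list(y_target = summary$plan@yTarget,
                       n_exact = summary$plan@nExact,
                       n_required = summary$plan@nRequired))
    if (!is.null(summary$impurity))
        x <- c(x, list(
            impurity_estimate_cells = summary$impurity@estimateCells,
            impurity_method = summary$impurity@method,
            assumed_efficiency = summary$impurity@assumedEfficiency))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}
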