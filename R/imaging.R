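# Per-well colony detection: stitching, per-channel segmentation, sieve
# filtering and dual-channel overlap calling.
#
# Connected components come from EBImage::bwlabel; everything downstream
# (scanline relabeling, feature measurement, sieve, overlap matching) is
# implemented here so the calling logic is fully specified and testable
# against a brute-force oracle.

#' Stitch four field-of-view tiles into one well raster
#'
#' Fields are placed in fixed 2x2 row-major order (1 = top-left,
#' 2 = top-right, 3 = bottom-left, 4 = bottom-right) with no registration
#' or overlap: tiles from a mechanical stage are assumed already aligned.
#' Pixel values are preserved exactly.
#'
#' @param fields list of 4 equally-shaped numeric matrices.
#' @return a matrix of twice the field height and width.
#' @examples
#' f <- matrix(7, 10, 10)
#' dim(stitchFields(list(f, f, f, f)))  # 20 20
#' @export
stitchFields <- function(fields) {
    if (!is.list(fields) || length(fields) != 4L)
        stop("stitchFields expects a list of exactly 4 fields")
    dims <- lapply(fields, dim)
    if (!all(vapply(dims, identical, logical(1), dims[[1]])))
        stop("all fields must have identical dimensions")
    rbind(cbind(fields[[1]], fields[[2]]),
          cbind(fields[[3]], fields[[4]]))
}

# Corrected digital contour length (Vossepoel & Smeulders): weights the
# straight and diagonal steps of the 8-connected boundary chain and
# subtracts a corner term, so a rasterized disk measures ~2*pi*r rather
# than the chain-code overestimate.
perimeterFromContour <- function(oc) {
    n <- nrow(oc)
    if (n <= 1L) return(1)
    d <- oc[c(seq(2L, n), 1L), , drop = FALSE] - oc
    manhattan <- abs(d[, 1]) + abs(d[, 2])
    ne <- sum(manhattan == 1)
    no <- sum(manhattan == 2)
    dirs <- paste(d[, 1], d[, 2])
    nc <- sum(dirs != dirs[c(n, seq_len(n - 1L))])
    max(0.980 * ne + 1.406 * no - 0.091 * nc, 1)
}

#' Segment one fluorescence channel into candidate regions
#'
#' Rough segmentation optionally smooths the raster with a Gaussian kernel
#' (\code{smoothingSigma} pixels; keeps pixel noise from shredding region
#' boundaries), thresholds it (pixels >= \code{segmentationThreshold} are
#' foreground, or an Otsu threshold when \code{thresholdMethod = "otsu"}),
#' labels 4-connected components, and applies a pre-sieve discarding
#' components smaller than \code{preSieveFraction * minArea} before
#' features are measured. \code{meanIntensity} is always measured on the
#' raw (unsmoothed) raster.
#' Candidates are labeled in deterministic scanline order (topmost, then
#' leftmost first pixel).
#'
#' @param raster 2-D numeric intensity matrix.
#' @param criteria a \code{DetectionCriteria}.
#' @param channel channel name recorded on the candidates.
#' @return list of \code{RegionCandidate} (empty when nothing segments).
#' @seealso [filterCandidates()], [callWell()]
#' @export
segmentChannel <- function(raster, criteria = DetectionCriteria(),
                           channel = "unknown") {
    stopifnot(is.matrix(raster))
    if (length(raster) == 0L) return(list())
    smoothed <- if (criteria@smoothingSigma > 0)
        matrix(EBImage::gblur(EBImage::Image(raster),
                              sigma = criteria@smoothingSigma),
               nrow(raster), ncol(raster))
    else raster
    thr <- if (criteria@thresholdMethod == "otsu") {
        mx <- max(smoothed)
        if (mx <= 0) Inf else EBImage::otsu(EBImage::Image(smoothed / mx),
                                            range = c(0, 1)) * mx
    } else criteria@segmentationThreshold
    mask <- smoothed >= thr
    if (!any(mask)) return(list())
    lab <- EBImage::bwlabel(mask)
    lab <- matrix(as.integer(lab), nrow(raster), ncol(raster))
    idx <- which(lab > 0L)
    byLabel <- split(idx, lab[idx])

    scale <- if (is.na(criteria@pixelScale)) 1 else criteria@pixelScale
    minAreaPx <- criteria@minArea / scale^2
    keep <- lengths(byLabel) >= criteria@preSieveFraction * minAreaPx
    byLabel <- byLabel[keep]
    if (!length(byLabel)) return(list())

    nr <- nrow(raster)
    # scanline (row-major) rank of each component's first pixel
    firstPix <- vapply(byLabel, function(px) {
        r <- (px - 1L) %% nr
        cc <- (px - 1L) %/% nr
        min(r * ncol(raster) + cc)
    }, numeric(1))
    byLabel <- byLabel[order(firstPix)]

    relab <- matrix(0L, nr, ncol(raster))
    for (i in seq_along(byLabel)) relab[byLabel[[i]]] <- i
    contours <- EBImage::ocontour(relab)

    out <- vector("list", length(byLabel))
    for (i in seq_along(byLabel)) {
        px <- byLabel[[i]]
        r <- (px - 1L) %% nr + 1L
        cc <- (px - 1L) %/% nr + 1L
        per <- perimeterFromContour(contours[[i]]) * scale
        areaPhys <- length(px) * scale^2
        out[[i]] <- new("RegionCandidate",
            channel = channel, label = i,
            area = areaPhys, perimeter = per,
            circularity = min(4 * pi * areaPhys / per^2, 1),
            meanIntensity = mean(raster[px]),
            centroid = c(mean(r), mean(cc)),
            pixels = as.integer(px),
            dim = dim(raster))
    }
    out
}

#' Sieve candidate regions by size, circularity and intensity
#'
#' Retains exactly the candidates with \code{area > minArea} AND
#' \code{circularity > minCircularity} AND
#' \code{meanIntensity > minMeanIntensity} — strict inequalities, so a
#' region sitting exactly at a threshold is rejected. Idempotent; output
#' is a subset of the input in the same order.
#'
#' @param candidates list of \code{RegionCandidate}.
#' @param criteria a \code{DetectionCriteria}.
#' @return the retained candidates.
#' @export
filterCandidates <- function(candidates, criteria = DetectionCriteria()) {
    keep <- vapply(candidates, function(cd) {
        cd@area > criteria@minArea &&
            cd@circularity > criteria@minCircularity &&
            cd@meanIntensity > criteria@minMeanIntensity
    }, logical(1))
    candidates[keep]
}

#' Call a well positive/negative from filtered candidates
#'
#' A colony is a (red, blue) candidate pair whose pixel overlap is at least
#' \code{overlapFraction} times the smaller candidate's pixel area; live
#' colonies take up both stains, while debris is typically single-channel,
#' so the dual-channel requirement is the main false-positive guard.
#' Matching is one-to-one and greedy by descending overlap (ties broken by
#' scanline label order). When a bright-field raster is supplied and
#' \code{brightfieldContrast} is set, each matched pair must additionally
#' show bright-field contrast (|mean in footprint - image median| above the
#' configured value) to be confirmed.
#'
#' @param red,blue filtered \code{RegionCandidate} lists from the two
#'   fluorescence channels (same raster geometry).
#' @param brightfield optional bright-field raster.
#' @param criteria a \code{DetectionCriteria}.
#' @param wellId well coordinate recorded on the call.
#' @return a \code{WellCall}; \code{positive} holds exactly when at least
#'   one confirmed colony pair was found.
#' @export
callWell <- function(red, blue, brightfield = NULL,
                     criteria = DetectionCriteria(), wellId = "A01") {
    pairs <- NULL
    if (length(red) && length(blue)) {
        pairs <- expand.grid(r = seq_along(red), b = seq_along(blue))
        pairs$overlap <- mapply(function(i, j)
            length(intersect(red[[i]]@pixels, blue[[j]]@pixels)),
            pairs$r, pairs$b)
        pairs$minArea <- mapply(function(i, j)
            min(length(red[[i]]@pixels), length(blue[[j]]@pixels)),
            pairs$r, pairs$b)
        pairs <- pairs[pairs$overlap >=
                       criteria@overlapFraction * pairs$minArea, ,
                       drop = FALSE]
        pairs <- pairs[order(-pairs$overlap, pairs$r, pairs$b), ,
                       drop = FALSE]
    }
    nColonies <- 0L
    if (!is.null(pairs) && nrow(pairs)) {
        usedR <- logical(length(red)); usedB <- logical(length(blue))
        bfMedian <- if (!is.null(brightfield)) stats::median(brightfield)
        for (k in seq_len(nrow(pairs))) {
            i <- pairs$r[k]; j <- pairs$b[k]
            if (usedR[i] || usedB[j]) next
            confirmed <- TRUE
            if (!is.null(brightfield) &&
                !is.na(criteria@brightfieldContrast)) {
                fp <- union(red[[i]]@pixels, blue[[j]]@pixels)
                confirmed <- abs(mean(brightfield[fp]) - bfMedian) >
                    criteria@brightfieldContrast
            }
            if (confirmed) {
                usedR[i] <- TRUE; usedB[j] <- TRUE
                nColonies <- nColonies + 1L
            }
        }
    }
    WellCall(wellId = wellId, colonyCount = nColonies,
             candidates = c(red, blue))
}

#' Detect colonies in a whole well image
#'
#' The full per-well pipeline: stitch the four fields (when present),
#' segment the red and blue channels, sieve by the detection criteria, and
#' call dual-channel colonies, with optional bright-field confirmation.
#' Deterministic: the same image and criteria always give the same call.
#'
#' @param image a \code{WellImage}.
#' @param criteria a \code{DetectionCriteria}.
#' @return a \code{WellCall} for the well.
#' @examples
#' truth <- GroundTruth(colonies = data.frame(row = 128, col = 128,
#'                                            radius = 60))
#' img <- generateWellImage(truth, shape = c(256, 256), seed = 1)
#' detectWell(img)
#' @export
detectWell <- function(image, criteria = DetectionCriteria()) {
    for (ch in c("red", "blue", "brightfield"))
        if (is.null(image@channels[[ch]]))
            stop("missing required channel: ", ch)
    getChannel <- function(ch) {
        x <- image@channels[[ch]]
        if (is.list(x)) stitchFields(x) else x
    }
    red <- filterCandidates(
        segmentChannel(getChannel("red"), criteria, "red"), criteria)
    blue <- filterCandidates(
        segmentChannel(getChannel("blue"), criteria, "blue"), criteria)
    callWell(red, blue, brightfield = getChannel("brightfield"),
             criteria = criteria, wellId = image@wellId)
}
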