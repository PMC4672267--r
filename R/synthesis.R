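# Synthetic well rendering with known ground truth, plus raster file I/O.
#
# The generator emulates the appearance of a sedimented, dissolved-agar
# well: bright, roughly circular dual-channel colonies over a dim
# carrier-cell background, with planted debris (single-channel disks,
# elongated bars, sub-criteria specks) as false-positive bait, and a
# bright-field channel in which objects appear dark.

# Additive super-Gaussian profile: peak * exp(-u^4) with u the (optionally
# elliptical, rotated) normalized radius. Flat-topped with a smooth edge,
# like a focused colony after sedimentation.
addBlob <- function(mat, row, col, a, b = a, angle = 0, peak) {
    nr <- nrow(mat); nc <- ncol(mat)
    ext <- ceiling(max(a, b) * 1.6)
    r0 <- max(1L, floor(row - ext)); r1 <- min(nr, ceiling(row + ext))
    c0 <- max(1L, floor(col - ext)); c1 <- min(nc, ceiling(col + ext))
    rr <- r0:r1; cc <- c0:c1
    dr <- outer(rr - row, rep(1, length(cc)))
    dc <- outer(rep(1, length(rr)), cc - col)
    ca <- cos(angle); sa <- sin(angle)
    u <- sqrt(((dr * ca + dc * sa) / a)^2 + ((-dr * sa + dc * ca) / b)^2)
    mat[rr, cc] <- mat[rr, cc] + peak * exp(-u^4)
    mat
}

#' Render a synthetic well image from planted ground truth
#'
#' Colonies are rendered as radially smoothed (flat-topped, soft-edged)
#' disks present in both fluorescence channels with peak intensity well
#' above the default detection criteria; debris objects are rendered
#' according to their kind so that each fails at least one criterion by
#' construction (\code{mono-*}: one channel only; \code{bar}: elongated,
#' low circularity; \code{speck}: below the area criterion). All objects
#' appear as dark features on the bright-field channel. Additive Gaussian
#' noise with the given SD is applied to every channel, and the result is
#' clipped to [0, intensityScale]. Fully reproducible: the same arguments
#' and seed give bit-identical images.
#'
#' @param truth a \code{GroundTruth}.
#' @param shape integer (rows, cols) of the rendered well raster.
#' @param noiseSd Gaussian noise SD in intensity units (default 5).
#' @param backgroundLevel fluorescence background level (default 10).
#' @param seed integer seed for the noise.
#' @param colonyPeak peak added intensity of colonies and bright debris
#'   (default 200, i.e. twice the default intensity criterion).
#' @param intensityScale maximum representable intensity (default 255).
#' @param wellId well coordinate recorded on the image.
#' @param fieldsPerWell 1 (default) or 4; with 4, the rendered raster is
#'   split into 2x2 row-major tiles so that \code{\link{stitchFields}}
#'   recovers it exactly (shape must then be even).
#' @return a \code{WellImage} with channels red, blue, brightfield.
#' @seealso [detectWell()] for the closed detection loop.
#' @export
generateWellImage <- function(truth, shape = c(512L, 512L), noiseSd = 5,
                              backgroundLevel = 10, seed = 1L,
                              colonyPeak = 200, intensityScale = 255,
                              wellId = "A01", fieldsPerWell = 1L) {
    validObject(truth)
    nr <- shape[1]; nc <- shape[2]
    objects <- rbind(
        if (nrow(truth@colonies))
            data.frame(row = truth@colonies$row, col = truth@colonies$col,
                       ext = truth@colonies$radius),
        if (nrow(truth@debris))
            data.frame(row = truth@debris$row, col = truth@debris$col,
                       ext = truth@debris$size))
    if (!is.null(objects) && nrow(objects)) {
        bad <- objects$row - objects$ext < 1 |
               objects$row + objects$ext > nr |
               objects$col - objects$ext < 1 |
               objects$col + objects$ext > nc
        if (any(bad))
            stop(sum(bad), " planted object(s) fall outside the ",
                 nr, "x", nc, " raster")
    }

    red <- matrix(backgroundLevel, nr, nc)
    blue <- matrix(backgroundLevel, nr, nc)
    bf <- matrix(0.8 * intensityScale, nr, nc)

    set.seed(seed)
    for (i in seq_len(nrow(truth@colonies))) {
        co <- truth@colonies[i, ]
        red <- addBlob(red, co$row, co$col, co$radius, peak = colonyPeak)
        blue <- addBlob(blue, co$row, co$col, co$radius, peak = colonyPeak)
        bf <- addBlob(bf, co$row, co$col, co$radius,
                      peak = -0.4 * intensityScale)
    }
    for (i in seq_len(nrow(truth@debris))) {
        de <- truth@debris[i, ]
        angle <- stats::runif(1, 0, pi)
        a <- de$size; b <- de$size
        if (de$kind == "bar") b <- de$size / 8
        inRed <- de$kind %in% c("mono-red", "bar", "speck")
        inBlue <- de$kind %in% c("mono-blue", "bar", "speck")
        if (inRed) red <- addBlob(red, de$row, de$col, a, b, angle,
                                  colonyPeak)
        if (inBlue) blue <- addBlob(blue, de$row, de$col, a, b, angle,
                                    colonyPeak)
        bf <- addBlob(bf, de$row, de$col, a, b, angle,
                      peak = -0.4 * intensityScale)
    }

    clip <- function(m) pmin(pmax(m, 0), intensityScale)
    if (noiseSd > 0) {
        red <- red + matrix(stats::rnorm(nr * nc, 0, noiseSd), nr, nc)
        blue <- blue + matrix(stats::rnorm(nr * nc, 0, noiseSd), nr, nc)
        bf <- bf + matrix(stats::rnorm(nr * nc, 0, noiseSd), nr, nc)
    }
    channels <- list(red = clip(red), blue = clip(blue),
                     brightfield = clip(bf))
    if (fieldsPerWell == 4L) {
        if (nr %% 2L || nc %% 2L)
            stop("4-field rendering needs even raster dimensions")
        channels <- lapply(channels, function(m) {
            hr <- nr %/% 2L; hc <- nc %/% 2L
            list(m[1:hr, 1:hc], m[1:hr, (hc + 1L):nc],
                 m[(hr + 1L):nr, 1:hc], m[(hr + 1L):nr, (hc + 1L):nc])
        })
    }
    WellImage(wellId = wellId, channels = channels,
              fieldsPerWell = fieldsPerWell,
              intensityScale = intensityScale)
}

channelFileName <- function(wellId, channel, field = NULL,
                            format = "tiff") {
    ext <- if (format == "png") "png" else "tif"
    if (is.null(field)) sprintf("%s_%s.%s", wellId, channel, ext)
    else sprintf("%s_%s_f%d.%s", wellId, channel, field, ext)
}

writeRaster <- function(mat, path, scale, format, bits) {
    m <- pmin(pmax(mat / scale, 0), 1)
    if (format == "png") png::writePNG(m, path)
    else tiff::writeTIFF(m, path, bits.per.sample = bits)
}

readRaster <- function(path, scale) {
    m <- if (grepl("\\.png$", path, ignore.case = TRUE))
        png::readPNG(path)
    else tiff::readTIFF(path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m * scale
}

#' Write / read well images as per-channel raster files
#'
#' One grayscale file per channel (and per field when the image holds four
#' fields), named \code{<well_id>_<channel>[_f<1-4>].tif} (or .png).
#' Intensities are stored normalized by \code{intensityScale}; 16-bit TIFF
#' is the default, which preserves an 8-bit-scale image to within
#' quantization (< 0.01 intensity units).
#'
#' @param image a \code{WellImage}.
#' @param dir directory to write into (created if needed).
#' @param format "tiff" or "png".
#' @param bits bits per sample for TIFF output (8 or 16).
#' @return invisibly, the written file paths.
#' @export
writeWellImage <- function(image, dir, format = c("tiff", "png"),
                           bits = 16L) {
    format <- match.arg(format)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character()
    for (ch in names(image@channels)) {
        x <- image@channels[[ch]]
        if (is.list(x)) {
            for (k in seq_along(x)) {
                p <- file.path(dir, channelFileName(image@wellId, ch, k,
                                                    format))
                writeRaster(x[[k]], p, image@intensityScale, format, bits)
                paths <- c(paths, p)
            }
        } else {
            p <- file.path(dir, channelFileName(image@wellId, ch, NULL,
                                                format))
            writeRaster(x, p, image@intensityScale, format, bits)
            paths <- c(paths, p)
        }
    }
    invisible(paths)
}

#' @rdname writeWellImage
#' @param wellId well coordinate whose files to read.
#' @param intensityScale intensity scale to restore on read.
#' @export
readWellImage <- function(dir, wellId, intensityScale = 255) {
    channels <- list()
    fields <- 1L
    for (ch in c("red", "blue", "brightfield")) {
        pat <- sprintf("^%s_%s(_f[1-4])?\\.(tif|tiff|png)$", wellId, ch)
        files <- sort(list.files(dir, pattern = pat))
        if (!length(files))
            stop("no ", ch, " channel file for well ", wellId, " in ", dir)
        if (length(files) == 1L && !grepl("_f[1-4]\\.", files)) {
            channels[[ch]] <- readRaster(file.path(dir, files),
                                         intensityScale)
        } else {
            if (length(files) != 4L)
                stop("well ", wellId, " channel ", ch, ": expected 4 ",
                     "field files, found ", length(files))
            channels[[ch]] <- lapply(file.path(dir, files), readRaster,
                                     scale = intensityScale)
            fields <- 4L
        }
    }
    WellImage(wellId = wellId, channels = channels, fieldsPerWell = fields,
              intensityScale = intensityScale)
}

#' List well ids present in an image directory
#'
#' @param dir directory of \code{<well>_<channel>[_f<k>].tif/png} files.
#' @return sorted character vector of well ids.
#' @export
listWellIds <- function(dir) {
    files <- list.files(dir,
        pattern = "^[A-Z][0-9]{2}_(red|blue|brightfield)(_f[1-4])?\\.(tif|tiff|png)$")
    ids <- unique(sub("_.*$", "", files))
    ids[wellOrder(ids)]
}
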