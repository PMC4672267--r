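test_that("stitching places 2x2 row-major tiles exactly", {
    f <- matrix(7, 100, 100)
    out <- stitchFields(list(f, f, f, f))
    expect_equal(dim(out), c(200L, 200L))
    expect_true(all(out == 7))

    set.seed(42)
    tiles <- lapply(1:4, function(i) matrix(runif(50 * 60), 50, 60))
    out <- stitchFields(tiles)
    expect_identical(out[1:50, 1:60], tiles[[1]])
    expect_identical(out[1:50, 61:120], tiles[[2]])
    expect_identical(out[51:100, 1:60], tiles[[3]])
    expect_identical(out[51:100, 61:120], tiles[[4]])

    expect_error(stitchFields(list(f, f, f)), "4 fields")
    expect_error(stitchFields(list(f, f, f, matrix(0, 10, 10))),
                 "identical dimensions")
})

test_that("stitching then cropping quadrants recovers the fields", {
    for (seed in 1:5) {
        set.seed(seed)
        tiles <- lapply(1:4, function(i) matrix(rpois(30 * 40, 50), 30, 40))
        out <- stitchFields(tiles)
        back <- list(out[1:30, 1:40], out[1:30, 41:80],
                     out[31:60, 1:40], out[31:60, 41:80])
        expect_identical(back, tiles)
    }
})

test_that("segmentation of an empty or blank raster yields nothing", {
    expect_equal(segmentChannel(matrix(0, 64, 64)), list())
    expect_equal(segmentChannel(matrix(numeric(), 0, 0)), list())
})

test_that("a hard disk segments to one candidate with disk geometry", {
    m <- diskRaster(256, radius = 60)
    cand <- segmentChannel(m, DetectionCriteria(), "red")
    expect_length(cand, 1)
    cd <- cand[[1]]
    expect_lt(abs(cd@area / (pi * 60^2) - 1), 0.05)
    expect_gt(cd@circularity, 0.9)
    expect_equal(cd@meanIntensity, 200, tolerance = 0.05)
    expect_equal(cd@centroid, c(128, 128), tolerance = 0.01)
    expect_equal(cd@channel, "red")
})

test_that("two disjoint disks give two scanline-ordered candidates", {
    m <- diskRaster(256, centre = c(190, 70), radius = 40)
    m[diskRaster(256, centre = c(60, 180), radius = 30) > 100] <- 200
    cand <- segmentChannel(m, rawCriteria(), "blue")
    expect_length(cand, 2)
    expect_equal(vapply(cand, slot, integer(1), "label"), c(1L, 2L))
    # scanline order: the topmost object (row 60) comes first
    expect_lt(cand[[1]]@centroid[1], cand[[2]]@centroid[1])
    # pixel sets match a brute-force flood fill of the same mask
    oracle <- floodFillComponents(m >= 100)
    expect_identical(lapply(cand, function(cd) sort(cd@pixels)), oracle)
})

test_that("segmentation equals a brute-force connected-components oracle", {
    crit <- rawCriteria(minArea = 1, preSieveFraction = 0,
                        segmentationThreshold = 1)
    for (seed in 1:10) {
        set.seed(seed)
        mask <- matrix(runif(40 * 40) < 0.35, 40, 40)
        cand <- segmentChannel(mask * 255, crit)
        oracle <- floodFillComponents(mask)
        expect_length(cand, length(oracle))
        expect_identical(lapply(cand, function(cd) sort(cd@pixels)),
                         oracle)
        # areas agree with component sizes
        expect_equal(vapply(cand, slot, numeric(1), "area"),
                     lengths(oracle))
    }
})

test_that("the pre-sieve drops sub-fragment components", {
    m <- diskRaster(256, radius = 60)
    m[10, 10] <- 200  # isolated bright pixel, far below 1% of minArea
    cand <- segmentChannel(m, rawCriteria())
    expect_length(cand, 1)
    expect_gt(cand[[1]]@area, 1000)
})

test_that("sieve filtering applies strict inequalities on all criteria", {
    mk <- function(area, circ, mi) {
        new("RegionCandidate", channel = "red", label = 1L, area = area,
            perimeter = sqrt(4 * pi * area / max(circ, 1e-6)),
            circularity = circ, meanIntensity = mi, centroid = c(1, 1),
            pixels = 1L, dim = c(10L, 10L))
    }
    crit <- DetectionCriteria()
    keep <- mk(6500, 0.8, 150)
    expect_length(filterCandidates(list(keep), crit), 1)
    # boundary values are rejected: the criteria are strict
    expect_length(filterCandidates(list(mk(6000, 0.8, 150)), crit), 0)
    expect_length(filterCandidates(list(mk(6500, 0.4, 150)), crit), 0)
    expect_length(filterCandidates(list(mk(6500, 0.8, 100)), crit), 0)
    # brute-force predicate scan over a random candidate list
    set.seed(1)
    cands <- lapply(1:50, function(i)
        mk(runif(1, 3000, 9000), runif(1), runif(1, 50, 200)))
    got <- filterCandidates(cands, crit)
    want <- Filter(function(cd) cd@area > 6000 && cd@circularity > 0.4 &&
                       cd@meanIntensity > 100, cands)
    expect_identical(got, want)
    # subset of input and idempotent
    expect_true(all(vapply(got, function(g)
        any(vapply(cands, identical, logical(1), g)), logical(1))))
    expect_identical(filterCandidates(got, crit), got)
})

test_that("well calling requires dual-channel overlap", {
    img <- generateWellImage(
        GroundTruth(colonies = data.frame(row = 128, col = 128,
                                          radius = 60)),
        shape = c(256, 256), seed = 1)
    crit <- DetectionCriteria()
    red <- filterCandidates(segmentChannel(img@channels$red, crit, "red"),
                            crit)
    blue <- filterCandidates(segmentChannel(img@channels$blue, crit,
                                            "blue"), crit)
    call <- callWell(red, blue, criteria = crit, wellId = "B05")
    expect_true(call@positive)
    expect_equal(call@colonyCount, 1L)
    expect_equal(call@wellId, "B05")
    # a red candidate with no blue partner is not a colony
    call2 <- callWell(red, list(), criteria = crit)
    expect_false(call2@positive)
    expect_equal(call2@colonyCount, 0L)
})

test_that("each candidate joins at most one colony (greedy matching)", {
    # two overlapping red disks vs one blue disk: only one pair can match
    red <- segmentChannel(diskRaster(256, c(128, 128), 60), rawCriteria(),
                          "red")
    red2 <- segmentChannel(diskRaster(256, c(128, 140), 60), rawCriteria(),
                           "red")
    blue <- segmentChannel(diskRaster(256, c(128, 130), 60), rawCriteria(),
                           "blue")
    red2[[1]]@label <- 2L
    call <- callWell(c(red, red2), blue, criteria = DetectionCriteria())
    expect_equal(call@colonyCount, 1L)
})

test_that("planted colonies are recovered and debris excluded", {
    truth <- GroundTruth(
        colonies = data.frame(row = c(110, 110, 390),
                              col = c(110, 390, 390), radius = 60),
        debris = data.frame(
            row = c(390, 250, 250, 250, 60),
            col = c(110, 64, 250, 430, 250),
            kind = c("mono-red", "mono-blue", "bar", "speck", "speck"),
            size = c(60, 50, 100, 15, 15)))
    img <- generateWellImage(truth, shape = c(512, 512), seed = 9)
    call <- detectWell(img)
    expect_equal(call@colonyCount, 3L)
})

test_that("rendering is deterministic and respects blank truth", {
    blank <- GroundTruth()
    img0 <- generateWellImage(blank, shape = c(128, 128), noiseSd = 0,
                              seed = 1)
    expect_true(all(img0@channels$red == 10))
    expect_true(all(img0@channels$blue == 10))
    a <- generateWellImage(blank, shape = c(128, 128), seed = 7)
    b <- generateWellImage(blank, shape = c(128, 128), seed = 7)
    expect_identical(a@channels, b@channels)
    cc <- generateWellImage(blank, shape = c(128, 128), seed = 8)
    expect_false(identical(a@channels$red, cc@channels$red))
})

test_that("objects outside the raster are rejected", {
    truth <- GroundTruth(colonies = data.frame(row = 20, col = 64,
                                               radius = 60))
    expect_error(generateWellImage(truth, shape = c(128, 128)),
                 "outside")
})

test_that("a planted colony is recovered near its true centroid", {
    for (seed in 1:5) {
        set.seed(seed)
        r0 <- runif(1, 55, 70)
        pos <- runif(2, 130, 380)
        truth <- GroundTruth(colonies = data.frame(row = pos[1],
                                                   col = pos[2],
                                                   radius = r0))
        img <- generateWellImage(truth, shape = c(512, 512), seed = seed)
        crit <- DetectionCriteria()
        red <- filterCandidates(
            segmentChannel(img@channels$red, crit, "red"), crit)
        expect_length(red, 1)
        expect_lt(sqrt(sum((red[[1]]@centroid - pos)^2)), r0 / 2)
    }
})

test_that("detectWell stitches 4-field images and errors on missing channels", {
    truth <- GroundTruth(colonies = data.frame(row = 128, col = 128,
                                               radius = 60))
    whole <- generateWellImage(truth, shape = c(256, 256), seed = 3)
    split <- generateWellImage(truth, shape = c(256, 256), seed = 3,
                               fieldsPerWell = 4L)
    expect_identical(stitchFields(split@channels$red),
                     whole@channels$red)
    expect_equal(detectWell(split)@colonyCount,
                 detectWell(whole)@colonyCount)
    broken <- whole
    broken@channels$blue <- NULL
    expect_error(detectWell(broken), "blue")
})

test_that("bright-field confirmation can veto a fluorescence-only pair", {
    truth <- GroundTruth(colonies = data.frame(row = 128, col = 128,
                                               radius = 60))
    img <- generateWellImage(truth, shape = c(256, 256), seed = 2)
    # colonies are dark on bright-field: contrast check passes
    crit <- DetectionCriteria(brightfieldContrast = 20)
    expect_equal(detectWell(img, crit)@colonyCount, 1L)
    # flat bright-field provides no contrast: the pair is vetoed
    img@channels$brightfield <- matrix(200, 256, 256)
    expect_equal(detectWell(img, crit)@colonyCount, 0L)
    # with the check disabled (default) the flat bright-field is ignored
    expect_equal(detectWell(img)@colonyCount, 1L)
})

test_that("well images round-trip through 16-bit TIFF files", {
    dir <- withr::local_tempdir()
    truth <- GroundTruth(colonies = data.frame(row = 64, col = 64,
                                               radius = 40))
    img <- generateWellImage(truth, shape = c(128, 128), seed = 4,
                             wellId = "C07")
    writeWellImage(img, dir)
    expect_true(file.exists(file.path(dir, "C07_red.tif")))
    back <- readWellImage(dir, "C07")
    expect_equal(back@channels$red, img@channels$red, tolerance = 1e-3)
    expect_equal(listWellIds(dir), "C07")
    # 4-field layout round-trips too
    img4 <- generateWellImage(truth, shape = c(128, 128), seed = 4,
                              wellId = "D02", fieldsPerWell = 4L)
    writeWellImage(img4, dir)
    back4 <- readWellImage(dir, "D02")
    expect_equal(back4@fieldsPerWell, 4L)
    expect_equal(stitchFields(back4@channels$blue),
                 stitchFields(img4@channels$blue), tolerance = 1e-3)
})

test_that("a modest batch of blank wells yields no false positives", {
    # a fast screen at module scale; the full 500-well screen runs in the
    # acceptance suite
    calls <- vapply(1:50, function(seed) {
        img <- generateWellImage(GroundTruth(), shape = c(256, 256),
                                 seed = seed)
        detectWell(img)@positive
    }, logical(1))
    expect_equal(sum(calls), 0L)
})
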