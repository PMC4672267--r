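# Fixtures are generated in code; no binary data on disk.

# record with given per-well colony counts (length = nWells)
makeRecord <- function(counts, experimentId = "exp1", design = NULL) {
    ids <- makeWellIds(length(counts))
    wells <- mapply(WellCall, wellId = ids,
                    colonyCount = as.integer(counts),
                    SIMPLIFY = FALSE, USE.NAMES = FALSE)
    ExperimentRecord(experimentId = experimentId, wells = wells,
                     design = design)
}

# the five 80-well experiments with one positive well in three of them
fig4Records <- function() {
    lapply(1:5, function(i) {
        counts <- integer(80)
        if (i <= 3) counts[i] <- 1L
        makeRecord(counts, experimentId = paste0("exp", i))
    })
}

randomRecord <- function(nWells, seed, maxCount = 3L) {
    set.seed(seed)
    makeRecord(sample(0:maxCount, nWells, replace = TRUE,
                      prob = c(0.8, 0.1, 0.07, 0.03)))
}

# brute-force 4-connected flood-fill labeling; returns list of sorted
# linear pixel index vectors, ordered by scanline (row-major) first pixel
floodFillComponents <- function(mask) {
    nr <- nrow(mask); nc <- ncol(mask)
    seen <- matrix(FALSE, nr, nc)
    comps <- list()
    for (start in which(mask)) {
        if (seen[start]) next
        stack <- integer(sum(mask)); stack[1] <- start; top <- 1L
        seen[start] <- TRUE
        px <- integer()
        while (top > 0L) {
            i <- stack[top]; top <- top - 1L
            px <- c(px, i)
            r <- (i - 1L) %% nr + 1L
            nbrs <- c(if (r > 1L) i - 1L, if (r < nr) i + 1L,
                      if (i > nr) i - nr, if (i <= nr * (nc - 1L)) i + nr)
            for (j in nbrs) {
                if (mask[j] && !seen[j]) {
                    seen[j] <- TRUE
                    top <- top + 1L; stack[top] <- j
                }
            }
        }
        comps[[length(comps) + 1L]] <- sort(px)
    }
    # scanline order of first pixel
    first <- vapply(comps, function(px) {
        r <- (px - 1L) %% nr; cc <- (px - 1L) %/% nr
        min(r * nc + cc)
    }, numeric(1))
    comps[order(first)]
}

# hard disk raster: constant `inside` within radius, `bg` outside
diskRaster <- function(n = 256, centre = c(n / 2, n / 2), radius = 60,
                       inside = 200, bg = 10) {
    d2 <- outer((seq_len(n) - centre[1])^2, (seq_len(n) - centre[2])^2,
                "+")
    m <- matrix(bg, n, n)
    m[d2 <= radius^2] <- inside
    m
}

# criteria with smoothing off (for exact mask-level comparisons)
rawCriteria <- function(...) DetectionCriteria(smoothingSigma = 0, ...)
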