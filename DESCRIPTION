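Package: digitalSACF
Title: Digital Analysis of Soft Agar Colony Formation Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Image-based detection of transformed-cell colonies in
    multi-well soft agar colony formation (SACF) assays, together with the
    digital (partitioned) statistical framework used to screen cell-therapy
    products for rare tumorigenic impurities. Provides per-well dual-channel
    fluorescence colony calling (stitching, segmentation, sieve filtering by
    size/circularity/intensity, two-channel overlap confirmation),
    Poisson-partition digital statistics (per-well negative rates,
    experiment and campaign false-negative rates, replicate planning,
    detection limits, colony-forming efficiency, most-probable-number
    impurity estimation), and a seeded Monte-Carlo simulator of whole assay
    campaigns with optional synthetic image rendering for closed-loop
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    EBImage,
    tiff,
    png,
    optparse
Suggests: testthat (>= 3.0.0), withr
biocViews: CellBasedAssays, Visualization, Classification
Config/testthat/edition: 3
RoxygenNote: 7.3.3
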