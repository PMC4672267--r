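---
title: "Methods: digital analysis of soft agar colony formation"
author: "digitalSACF authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital analysis of soft agar colony formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The assay model

A cell preparation suspected of harbouring rare transformed cells is
partitioned across $W$ wells of soft agar culture. Transformed cells grow
anchorage-independently into colonies; normal carrier cells (e.g. hMSCs)
die by anoikis and form none. After culture, colonies are dual-stained
(mitochondrial red, nuclear blue), the agar is dissolved so colonies
sediment into the imaging plane, and each well is imaged and reduced to a
binary call: *positive* if at least one confirmed colony is present. The
package implements everything downstream of the wet bench: the per-well
image analysis, the partition statistics, and a simulator that generates
both digital readouts and synthetic well images with known ground truth.

Three model assumptions run through the statistics:

1. **Independent wells.** Wells are independent partitions of a
   well-mixed suspension, so a fixed spike of $T$ cells lands
   multinomially across wells (per-well occupancy Binomial$(T, 1/W)$,
   Poisson-like for large $W$), and serial dilution to a mean of
   $\lambda$ cells/well gives Poisson$(\lambda)$ occupancy.
2. **Per-cell Bernoulli colony formation.** Each dispensed transformed
   cell independently forms a detectable colony with probability $f$, the
   colony-forming efficiency. Cooperative effects (carrier-cell co-culture
   raises $f$ empirically) enter only through the value of $f$ supplied by
   the positive-control calibration; no mechanistic co-culture model is
   attempted. Pipetting losses before dispensing are likewise folded into
   $f$ — the assay cannot distinguish a cell that was never dispensed from
   one that failed to grow.
3. **Binary readout.** A well reports only positive/negative; the
   digital false-negative arithmetic uses the per-well negative rate $q$:
   one experiment misses with $x = q^W$, $n$ replicates with $y = x^n$,
   hence $n = \log y / \log x$ (rounded up) experiments bound the campaign
   false-negative rate at $y$.

The per-well rate $q$ is estimated by *pooling* wells across replicate
experiments (total negatives / total wells), which reproduces ratios like
$397/400 = 0.9925$ exactly; per-experiment averaging is available via
`estimateWellRate(..., pooled = FALSE)`. Where a published per-well rate
is supplied directly (e.g. 0.9956 for a 160-well design), it is treated as
an input constant rather than re-derived, since its derivation from raw
counts is not always reconstructible.

# Detection criteria and their defaults

`DetectionCriteria()` carries the sieve thresholds, all strict
inequalities:

| parameter | default | unit | role |
|---|---|---|---|
| `minArea` | 6000 | px² (or physical units² via `pixelScale`) | rejects specks and single cells |
| `minCircularity` | 0.4 | — | rejects elongated debris; form factor $4\pi A / P^2$ |
| `minMeanIntensity` | 100 | native intensity | rejects dim background structure |
| `segmentationThreshold` | 100 | native intensity | rough-segmentation cut |
| `smoothingSigma` | 2 | px | Gaussian pre-smoothing before thresholding |
| `overlapFraction` | 0.5 | — | minimum overlap / smaller area for a red–blue match |
| `brightfieldContrast` | NA (off) | native intensity | optional bright-field confirmation |

The area and intensity defaults are expressed on an 8-bit-like native
scale; neither the physical unit of the area criterion nor the bit depth
of the intensity criterion is fixed by the assay definition, so both are
configuration, not assertion. `pixelScale` converts areas and perimeters
to physical units when the magnification is known. Whether the intensity
criterion means mean, maximum or integrated intensity is likewise an open
convention; this package uses the **mean raw intensity** over the region
and documents it in the candidate features.

Design choices worth making explicit:

- **Circularity** uses the form factor $4\pi A/P^2$ clamped to $[0,1]$,
  with the perimeter measured as a corrected digital contour length
  (Vossepoel–Smeulders weights $0.980 N_e + 1.406 N_o - 0.091 N_c$ on the
  8-connected boundary chain). A plain chain-code length overestimates a
  digital disk's perimeter by ~5%, dragging its form factor to ~0.91;
  the corrected estimator scores a rasterized disk at ~1.0, which is the
  behaviour a 0.4 disk-likeness threshold presumes.
- **Gaussian pre-smoothing** (`smoothingSigma = 2`) precedes
  thresholding. Without it, pixel noise at realistic levels shreds the
  region boundary: the measured form factor of a clean disk falls below
  0.4 once the noise SD reaches ~5% of the object's peak, and the sieve
  starts rejecting true colonies. Smoothing only affects the mask;
  `meanIntensity` is always measured on the raw raster. Setting
  `smoothingSigma = 0` recovers a literal pixelwise threshold (used by
  the connected-components oracle tests).
- **Segmentation** is a fixed global threshold by default (deterministic,
  auditable); Otsu's method is available per channel via
  `thresholdMethod = "otsu"` for images on other intensity scales.
- **Pre-sieve**: components below 1% of `minArea` are dropped before
  feature computation — the "rough segmentation then sieve" structure.
- **Overlap calling** is greedy one-to-one matching by descending pixel
  overlap (ties broken in scanline label order), requiring overlap
  $\ge$ `overlapFraction` × the smaller region's area. A fractional rule
  tolerates small registration/shape noise between channels while still
  demanding genuine colocalization; each candidate joins at most one
  colony so one smeared region cannot inflate the count.
- **Bright-field confirmation** is off by default: the automated proxy
  (mean in-footprint contrast against the image median) stands in for
  what is fundamentally a manual check, and the synthetic validation does
  not lean on it.
- **2-D only.** The agar-dissolution/sedimentation step exists precisely
  to collapse the assay into a single focal plane, so the software
  assumes sedimented, in-focus 2-D rasters; there is no z-stack handling.
- Stitching is a fixed 2×2 row-major tile placement with no registration,
  matching mechanical-stage fields.

# The synthetic well generator

`generateWellImage()` emulates the appearance this pipeline consumes:
colonies as flat-topped, soft-edged radial blobs
($I \propto e^{-(r/r_0)^4}$, peak 200 over background 10 by default)
present in both fluorescence channels; debris planted as false-positive
bait, each kind failing at least one criterion by construction
(single-channel disks, elongated bars with form factor ~0.3, sub-size
specks); a bright-field channel where objects appear dark; additive
Gaussian noise; strict clipping to the intensity range. One integer seed
makes images bit-reproducible.

What it deliberately does **not** model: carrier-cell background texture,
uneven illumination, stain spectral bleed-through, out-of-focus light,
agar remnants, or colony growth kinetics. Passing the synthetic screens
therefore demonstrates that the detector implements its stated criteria
correctly (geometry, channels, thresholds, overlap logic) — not that
those criteria are optimal for any particular microscope. On real data
the thresholds should be re-derived from positive-control wells.

Default study conditions used across tests: 512×512 wells, colony radius
60 px (area ≈ 1.9 × `minArea`), peak 200 (2 × the intensity criterion),
noise SD up to 20 (10% of peak) — conditions under which the blank-well
false-positive rate is 0 and per-colony recall is 1 across hundreds of
generated wells.

# Digital statistics: numerical choices

- `estimateWellRate` pools integer counts and divides once; no floating
  accumulation.
- `requiredExperiments` returns both the exact $\log y / \log x$ and its
  ceiling; the plan always satisfies $x^{n} \le y$. $x \ge 1$ is an
  error — no number of replicates can bound the false-negative rate.
- `llod` defaults to the sample SD ($n-1$); the population-SD convention
  is a flag, since control-lot conventions vary and with $n = 3$ lots the
  difference is material.
- The MPN estimator $\hat\lambda = -\ln(\text{negative fraction})/f$
  requires at least one negative well (otherwise unbounded, an error) and
  agrees with the colony-ratio estimator to first order when positives
  are rare; the two diverge as wells saturate, where MPN corrects for
  colony co-occupancy. Bootstrap CIs resample wells with replacement
  (2000 draws, seeded, percentile interval) and are an extension beyond
  the published procedure, labelled as such.
- `detectionProbability` returns $1-(1-f)^T$ for fixed spikes — the
  partition layout cancels out under per-cell independence — and the
  per-well rate $1-e^{-\lambda f}$ for Poisson dispensing
  (`expectedPositiveWells` gives the per-experiment expectation
  $W(1-e^{-\lambda f})$).

# Simulator design

- Fixed-spike designs partition exactly $T$ cells multinomially (the
  spiking experiments physically place one cell); Poisson-dispensed
  designs draw per-well counts at mean $\lambda$ (the efficiency
  designs at 0.5 cells/well). Both conserve or generate counts cell by
  cell, and colony counts never exceed cell counts.
- One master seed deterministically derives one sub-seed per simulated
  experiment, so any replicate can be reproduced in isolation.
- `keepRecords = FALSE` skips materializing per-well objects for large
  power runs; the RNG stream, detection frequency and histogram are
  identical to the record-keeping path.
- With `renderImages = TRUE` every simulated well is rendered and read
  back through `detectWell` — within the generator's sensitivity
  envelope the closed loop reproduces the direct digital readout
  record-for-record.

# Problem sizes in the shipped tests

The test suite validates stochastic claims at sizes chosen to keep Monte
Carlo error meaningful while remaining desk-scale: 10,000 replicates for
detection-frequency consistency (3 standard errors ≈ 0.014), 1000
replications of the three-plate efficiency recovery, 2000 partitions for
the occupancy goodness-of-fit, and 500-well synthetic screens for the
false-positive and recall properties. The acceptance script re-runs the
efficiency recovery at 1000 replications from a user-supplied seed.

# Known limitations

- The detector is calibrated in pixel units; applying it to a new imaging
  configuration requires setting `pixelScale` or re-deriving `minArea`.
- Touching colonies merge into one connected component and are counted
  once; the assay regime of interest (0–few colonies per well) makes this
  rare, and the simulator's placement keeps rendered colonies separated.
- The MPN interval does not propagate uncertainty in $f$; the efficiency
  is treated as known from the positive-control calibration.
- Single-channel debris overlapping a true colony of the other channel
  could in principle pair with it; the overlap fraction and one-to-one
  matching bound, but do not eliminate, this failure mode.
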