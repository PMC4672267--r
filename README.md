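# digitalSACF

Quality control of cell-therapy products requires ruling out rare
tumorigenic cells hiding in a vast excess of normal carrier cells — for
example a single transformed cell among 10 million human mesenchymal stem
cells (hMSCs, 0.00001%). The soft agar colony formation (SACF) assay
detects such cells by their anchorage-independent growth: transformed
cells form colonies in soft agar, while normal adherent cells die by
anoikis. `digitalSACF` implements the *digital* version of this assay —
the cell preparation is partitioned across many wells, each well is imaged
and read out as a binary positive/negative colony call, and the binary
pattern is analysed with Poisson partition statistics — together with the
image-analysis pipeline that produces the per-well calls and a Monte-Carlo
simulator for validating assay designs before committing plates.

## What it computes

**Colony detection.** Each well is imaged in three channels (red
mitochondrial stain, blue nuclear stain, bright-field), optionally as four
stitched fields. Per channel the image is roughly segmented (Gaussian
pre-smoothing, intensity threshold, connected components), then sieved by
strict criteria — area > 6000, form-factor circularity
4&pi;A/P&sup2; > 0.4, mean intensity > 100 — and a colony is confirmed only
where a red and a blue region overlap (&ge; 50% of the smaller region by
default). Live-cell colonies take up both stains; debris is typically
single-channel or misshapen, so the dual-channel rule suppresses false
positives. Bright-field contrast confirmation is available as an extra
check.

**Digital statistics.** With per-well negative rate *q* over *W* wells,
one experiment misses contamination with probability *x* = *q*^*W*; *n*
replicate experiments miss with *y* = *x*^*n*, so
*n* = log *y* / log *x* experiments bound the campaign false-negative rate
at *y*. The package estimates *q* by pooling replicate plates, plans *n*,
computes detection limits (mean + 3.3 SD of negative controls), estimates
colony-forming efficiency *f* (colonies per dispensed cell) from
positive-control plates, and converts digital readouts into impurity loads
by the colony ratio or a most-probable-number (MPN) estimator
&lambda; = &minus;ln(negative fraction)/*f* per well.

**Simulation.** `simulateCampaign()` spikes *T* cells into *W* wells
(multinomially, or Poisson-dispensed at a mean per-well count), forms
colonies per cell as Bernoulli(*f*), and can render every well as a
synthetic image and read it back through the detector — a closed loop that
exercises the whole pipeline against known ground truth.

## Worked example

```r
library(digitalSACF)

# five 80-well experiments; a single colony was found in three of them
records <- lapply(1:5, function(i) {
  counts <- integer(80); if (i <= 3) counts[1] <- 1L
  ExperimentRecord(paste0("exp", i),
    mapply(WellCall, makeWellIds(80), counts, SIMPLIFY = FALSE))
})

rate <- estimateWellRate(records)
rate
#> WellRateEstimate: p(negative) = 0.9925, p(positive) = 0.0075 (3/400 wells positive)

x <- experimentFalseNegative(pNegative(rate), 80)
signif(x, 4)
#> [1] 0.5476

requiredExperiments(x, yTarget = 0.01)
#> FalseNegativePlan: x = 0.5476, target y = 0.01 -> n = 7.646, 8 experiment(s) required

estimateImpurity(records, efficiency = 0.688, method = "mpn")
#> ImpurityEstimate (mpn): 4.377 cells at assumed efficiency 0.688
```

Reading: a well of this design is colony-free with probability 0.9925, so
a single 80-well experiment misses the contamination more than half the
time (x = 0.5476) — but eight replicate experiments push the campaign
false-negative rate below 1%. Assuming the impurity forms colonies like
the positive control (f = 0.688), the three observed positives correspond
to about 4.4 transformed cells across the pooled preparation.

The same numbers are available from the shell:

```sh
inst/scripts/digital-sacf plan --p-negative 0.9925 --wells 80 --target 0.01
```

and `detect`, `estimate` and `simulate` subcommands cover image
directories, plate-map CSVs and simulation configs (see `?sacfCLI`).

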