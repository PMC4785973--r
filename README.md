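# myomorph

Quantitative morphometry of remodelling muscles in time-lapse fluorescence
microscopy.

During *Drosophila* metamorphosis, the persistent dorsal internal oblique
muscles (DIOMs) of the pupal abdomen are remodelled rather than histolysed:
they atrophy roughly threefold over the first two days after head eversion
(HE), then regrow, while their myonuclei migrate through a reproducible
sequence of localization patterns (uniform basal spread → central cluster →
single row along the midline). Quantifying this from five-day, 30-minute
interval confocal time-lapse recordings requires a measurement pipeline:
manual contour + medial-axis annotations of maximum-intensity projections,
shape features per muscle per frame, alignment of every series to HE as time
zero, and rank-based group comparisons between RNAi genotypes.

`myomorph` implements that pipeline as a tested, reusable R package, and —
because the original image data are not publicly deposited — ships a seeded
synthetic two-channel time-lapse generator with exact analytic ground truth
so every stage can be validated end to end.

## What it computes

For a muscle ROI given as a closed contour polygon *C* and a medial-axis
polyline *M* (pixel coordinates, pixel size *s* in μm):

* **area** — shoelace area of *C* × *s*²  (μm²);
* **length** — arc length of *M* × *s*  (μm);
* **mean diameter** — sample points are placed every 5 px of arc length
  along *M*; at each point, rays are cast in both directions orthogonal to
  the local tangent and the chord is the sum of the distances to the nearest
  contour intersections on each side; the mean diameter is the arithmetic
  mean of the chords (μm).

Series are indexed in signed hours after head eversion,
*t* = (frame − he_frame) · Δt / 60, and compared on the canonical 13-point
grid {5, 10, 15, 20, 25, 30, 40, 50, 60, 70, 80, 90, 100} h aHE. Group
comparisons report per-grid-time medians with 25/75 percentiles and
tail-specific Mann–Whitney U p-values (minimum group size 5, p clipped to
[0.0001, 1], exact enumeration for small tie-free samples). Myonuclear
positions are decomposed into a normalized axial coordinate u ∈ [0, 1]
along the medial axis and a lateral offset from it; the distribution
metrics (axial SD, central fraction, midline score) drive a documented
rule-based classifier of the four localization patterns.

## Worked example

Simulate a control and a TOR-knockdown cohort (15 pupae each, 256 × 256
"fast" profile covering the 13 canonical time points), measure every ROI
with the morphometry core, and compare the genotypes:

```r
library(myomorph)

co  <- generate_cohort("control",   15, seed = 1, profile = "fast", render = FALSE)
tor <- generate_cohort("TOR_shRNA", 15, seed = 2, profile = "fast", render = FALSE)
feats <- measure_rois(c(co$rois, tor$rois), pixel_size = 1.25, step_px = 5)

at5   <- subset(feats, genotype == "control" & abs(hours_aHE - 5)   < 0.25)
at50  <- subset(feats, genotype == "control" & abs(hours_aHE - 50)  < 0.25)
at100 <- subset(feats, genotype == "control" & abs(hours_aHE - 100) < 0.25)
median(at5$area_um2)                                   # 17908 um^2
median(at5$mean_diameter_um)                           # 84.4  um
fold_change(median(at5$area_um2),  median(at50$area_um2),  "decline")   # 3.0
fold_change(median(at50$area_um2), median(at100$area_um2), "increase")  # 2.6

cmp <- compare_genotypes(feats, "area_um2", "TOR_shRNA", "control", tail = "left")
head(as.data.frame(cmp)[, c("grid_time", "n_a", "median_a", "median_b", "p", "significant")], 4)
#>   grid_time n_a median_a median_b     p significant
#> 1         5  15 13988.04 17907.62 1e-04        TRUE
#> 2        10  15 12745.39 16589.48 1e-04        TRUE
#> 3        15  15 11502.59 15271.12 1e-04        TRUE
#> 4        20  15 10259.64 13952.55 1e-04        TRUE
```

The measured control medians recover the generator's pinned trajectory
(17 925 → 6 038 → 15 719 μm²; 84.4 μm diameter at +5 h) to within polygon
discretization error, i.e. a threefold atrophy followed by a 2.6-fold
regrowth, and the left-tailed MWU flags the TOR deficit at every grid time.
`run_all(run_config(...))` performs the same sequence as a single
orchestrated run (simulate → measure → align → compare → nuclei → report)
and writes CSV/PNG/JSON outputs; `inst/cli/myomorph.R` exposes the stages
as shell subcommands.

## Vignette

`vignettes/muscle-remodelling-pipeline.Rmd` documents the measurement
model, the statistical contract, the synthetic generator's design (what it
emulates and what it deliberately does not), every tunable threshold, and
the package's known limitations.
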