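---
title: "Quantifying muscle remodelling from time-lapse projections"
author: "myomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying muscle remodelling from time-lapse projections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myomorph)
```

## The measurement problem

Persistent abdominal muscles of *Drosophila* pupae (DIOMs) are remodelled
during metamorphosis: they atrophy for roughly two days after head eversion
(HE), then hypertrophy, while rotating toward the pupal midline and
repositioning their nuclei. The observable is a five-day, two-channel
confocal time lapse (cytoplasmic reporter in channel 1, nuclear reporter in
channel 2), acquired at 30-minute intervals, z-projected to
maximum-intensity projections, and annotated by hand: a closed contour
around each muscle and a medial-axis (MA) polyline inside it, tracked by a
stable identity across frames.

`myomorph` turns those annotations into three shape features, aligns all
series to HE, and provides the group statistics and myonuclear metrics of
the analysis, plus a synthetic data generator that makes the whole chain
testable.

## Shape features

For a contour $C$ (sub-pixel polygon) and MA polyline $M$ with pixel size
$s$ (μm/px):

* **Area** is the shoelace area of the exact polygon times $s^2$. We use the
  vector polygon, not pixel counting, because the annotation *is* vector
  data; the absolute value makes it orientation-independent, and
  self-intersecting polygons are rejected rather than silently measured.
* **Length** is the MA arc length times $s$. It is invariant under vertex
  subdivision.
* **Mean diameter** samples the MA every `step_px = 5` pixels of arc length,
  starting at arc position 0 and ending at the last multiple of the step
  that does not exceed the total arc length (both MA endpoints are included
  when they fall on that grid). At each sample the local tangent is taken by
  central difference on the arc-length parameterization (one-sided at the
  ends), and rays are cast in the two orthogonal directions. Each ray
  contributes the distance to its *nearest intersection with the contour
  along the ray*; the chord is the sum of the two sides and the mean
  diameter is the unweighted mean of the chords. A ray that fails to hit the
  contour (an MA point outside the contour) is an error that names the
  offending sample, not a silent `NA`.

Two readings of "distance to the nearest contour on each side" are
possible: nearest intersection along the orthogonal ray (chosen), or
nearest contour point in any direction. The ray reading matches the notion
of an orthogonal chord and makes the constant-width rectangle exact, which
is the anchor case used in the tests.

Coordinates are 0-based pixel indices, x rightward, y downward, with a
pixel's centre at its integer coordinate. These conventions are arbitrary
but load-bearing: every module in the package shares them.

## Time model and alignment

HE onset is the temporal reference: frame $f$ maps to
$t = (f - f_{HE})\,\Delta t / 60$ signed hours aHE, an affine, invertible
map. Genotypes are compared on the canonical 13-point grid
`canonical_grid()` = {5, …, 30, 40, …, 100} h aHE (5-hour spacing early,
10-hour spacing late). Observations are matched to grid times by nearest
neighbour within a tolerance of 0.25 h — half the standard acquisition
interval, which guarantees a unique nearest frame — and are never
interpolated: a grid slot with no observation in tolerance stays empty.
HE detection itself is an annotation input (exact in synthetic data,
manual in real data); the package does not attempt to detect it.

The experiment store keeps `experiments`, `features` and `nuclei` as
relational tables with enforced keys (features only for registered samples,
one row per (sample, muscle, frame)) and persists them as a directory of
CSV files with exact round-trip. A client–server database would add
deployment burden without changing the contract the analysis needs:
relational queries and referential integrity.

## Group statistics

* **Medians and quartiles** use linear interpolation between order
  statistics (`quantile` type 7).
* **Mann–Whitney U** is the only inferential statistic. The contract is:
  minimum group size 5 (violations are errors, not p-values); tails `left`
  (A < B), `right` (A > B), `two`; exact enumeration of the rank
  distribution for tie-free samples with $m + n \le 20$, otherwise the
  normal approximation with continuity and tie (midrank) correction; and
  the returned p clipped to $[10^{-4}, 1]$. The floor and the minimum-n
  rule mirror the behaviour documented for the statistical library the
  original analysis used; the internals here are standard rank-sum
  machinery and are verified in the tests against a from-scratch
  enumeration oracle over all $\binom{m+n}{m}$ assignments.
* **Normalization** to a reference time (e.g. +5 h or +50 h) is computed
  per muscle *before* any aggregation — each muscle is expressed as a
  percentage of its own reference value — so cohort distributions of
  normalized values are meaningful and unit changes cancel exactly.
* **Fold changes** are reported with an explicit direction (`increase`
  = to/from, `decline` = from/to) and optional rounding, because published
  fold values are conventionally quoted to one decimal.
* **No multiple-testing correction** is applied across grid times: the
  analysis convention is raw per-timepoint p-values against a 0.05 line,
  and the package follows it (the comparison table carries everything
  needed to apply a correction downstream).
* Grid times where either group is smaller than 5 are reported as
  *untested* (`tested = FALSE`, `p = NA`) — never as p = 1, which would
  conflate "no evidence" with "tested and null".
* **Weighted-mean eclosion time** works in h.min notation (107.04 means
  107 h 04 min): rows are converted to minutes, weighted by the number of
  eclosed pupae, averaged, rounded to the nearest minute and re-formatted.
  The per-genotype table ships in `inst/extdata/eclosion_times.csv`.

## Myonuclear metrics and the pattern classifier

Each nuclear centroid is decomposed relative to its muscle's MA into a
normalized axial position $u \in [0, 1]$ (arc position of the nearest MA
point over MA length), an unsigned lateral distance (μm), a signed lateral
distance (the sign encodes the side of the axis), and the local radius
(half the chord at the nearest profile sample). Per muscle and time point,
`distribution_metrics()` reports the population SD of $u$ (bounded by 0.5),
the central fraction ($|u - 0.5| < 0.15$), and the midline score
(median lateral distance over local radius).

The observed localization phases are qualitative; the classifier makes the
boundaries explicit, configurable defaults:

1. axial SD < 0.15 → `central_cluster`;
2. otherwise midline score < 0.25 → `midline_row`;
3. otherwise, if ≥ 75% of nuclei sit on one side of the axis and the signed
   lateral spread is < 0.25 of the local radius → `uniform` (basal);
4. otherwise → `scattered`.

Rule 3 exists because, in 2-D projections, a uniform *basal* sheet and a
scattered distribution both sit off the midline; what distinguishes them is
side consistency and lateral spread. With true 3-D data the basal side
could be read from z directly; on projections this side-consistency
heuristic is the documented stand-in and is the main known limitation of
the classifier. The metric also does not distinguish one central cluster
from two; bimodality testing is noted as future work rather than guessed.

Phase timelines are majority-smoothed with a window of 3 (ties keep the
centre value) before transitions are reported, so a single misclassified
frame does not create a spurious transition.

`detect_nuclei()` (Otsu threshold computed inside the ROI, connected
components, minimum size, intensity-weighted centroids) is deliberately
separable from the metrics: classifier tests run on ground-truth centroids
so detector quality and classifier behaviour are assessed independently.

## The synthetic generator

The generator emulates the acquisition geometry (1024 × 1024 px at
1.25 μm/px, 30-min intervals, ~240 frames, HE at frame 24; 8-bit output)
and the measured phenotypes, with a **fast profile** (256 × 256 px,
only the 13 canonical time points) used by the tests and validation runs
so the suite stays fast.

**Capsule geometry.** Muscles are rendered as capsules — a rectangular
shaft of length $L$ with semicircular caps of diameter $D$ — because
capsules give closed-form truth: area $= LD + \pi (D/2)^2$, length $= L$
(the MA is the shaft), diameter $= D$. Real DIOMs are irregular; the
capsule trades realism for exact testability, which is the generator's
purpose. Area and diameter trajectories are piecewise-linear keyframes and
$L$ is *derived* from them via the capsule identity, so the three features
remain mutually consistent. Edges are rendered with a one-pixel linear
coverage ramp so the integrated intensity is an unbiased estimator of the
true area.

**Preset anchoring.** The control preset pins its keyframes to the
published control medians: area 17 925 → 6 038 → 15 719 μm² at
+5/+50/+100 h and diameter 84.4 → 24.4 μm with recovery to ~71% of the
+5 h value. Perturbation presets encode each phenotype's direction and
rough magnitude (TOR/Rheb: deeper atrophy, weak regrowth; Tsc2:
suppressed atrophy; Atg: attenuated atrophy with larger mid-pupation
diameter; yki: longer and thinner with a weaker HE contraction, factor
0.578 vs 0.53; Cp1: control-like atrophy, frozen nuclei, premature death
of 2/3 of muscles at 55.3 ± 13.4 h). Exact relative minima of the thin
presets are moderated where the capsule identity would otherwise force
implausibly long fibres — a capsule artifact, not a claim about the
biology.

**Cohort variation.** Each sample (pupa) carries one muscle whose area and
diameter keyframes are scaled by a single per-sample multiplier
$e^{0.1 z}$, constant over the trajectory. The $z$ are drawn by seeded
stratified (Latin-hypercube) sampling — a random permutation of the normal
quantiles $\Phi^{-1}((i - 0.5)/n)$, clamped to ±2 — rather than i.i.d.
draws. This keeps the marginal spread log-normal-like with σ = 0.1 while
pinning the cohort *median* trajectory to the preset keyframes by
construction, which is what makes median-recovery checks guarantees
instead of coin flips. The published data give no per-muscle variance;
σ = 0.1 is a stand-in chosen to resemble the spread of per-muscle line
plots, not an inference. Using one multiplier for both features (rather
than independent ones) reflects that large muscles are large in both area
and diameter, and keeps derived shaft lengths inside the rendered frame
for every seed.

**Nuclei programs.** Each preset carries an ordered phase list — control:
uniform basal from the start, central cluster from +40 h, midline row from
+50 h; Atg: scattered instead of the midline row; Cp1: a single uniform
phase (frozen positions). Between phases, nuclei interpolate linearly to
their new target positions over 10 h, matching the observed timing
(anti-polar migration beginning around +40 h, clusters at ~+50 h, polar
migration over the next ~10 h); the kinematics themselves are not reported
anywhere, so linear motion is the simplest choice. Pattern targets are
built so the classifier's defining statistics hold *by construction*:
cluster axial positions are clamped to 0.5 ± 0.09 (population SD < 0.1),
uniform/scattered axial positions are stratified (SD ≈ 0.29 > 0.2),
scattered lateral offsets avoid the 0.15-radius midline band.

**Noise and determinism.** Channel intensities get a constant background,
optional Poisson shot noise and Gaussian read noise, clipped to the bit
depth. Every random element — cohort multipliers, death-time assignment,
per-phase nucleus targets, per-frame noise — is drawn from a seed derived
deterministically from (scene seed, muscle, phase/frame), so identical
specs produce bit-identical output and any frame can be re-rendered in
isolation.

**What the generator does not model:** photobleaching, stage drift, pupal
autofluorescence, vacuoles, irregular fibre shapes, nucleus identity over
time. Passing tests on synthetic cohorts therefore demonstrates that the
measurement and statistics chain is correct *given* faithful annotations;
it does not certify segmentation of real images (which is manual in this
workflow) nor robustness to imaging artifacts outside the noise model.

## Imaging operations

`concatenate_volumes()` joins acquisitions along time after checking that
channel/z/y/x dimensions and spacing agree; `max_project()` produces the
MIP substrate and is idempotent on already-projected data.
`orthogonal_reslice()` samples a volume along an x-y polyline extended in
z and reports, per column, the z extent of signal above half the column
maximum, scaled by the z spacing. Half-maximum is the package's explicit
boundary criterion (the convention behind reported "mean depth" values is
not stated anywhere); with anisotropic voxels (1.25 vs 13.2 μm) depth is
accurate only to about one slice, which is why the corresponding test
allows 15%. Only multi-page TIFF is supported, with page order
(t, channel, z) declared in a YAML sidecar; proprietary microscope formats
are out of scope.

## Problem sizes and runtime choices

The test suite and the validation script use the fast profile with cohorts
of 15 pupae (12 for classifier recall, matching the smallest published
per-genotype muscle counts), which keeps a full run in tens of seconds
while exercising every code path; the full 240-frame 1024² profile is
available through `profile = "full"` for realistic-scale simulations.
Tolerances in the tests reflect the error sources actually present:
polygon discretization of the caps (< 2% on area), chord sampling (< 5% on
diameter), one z slice on depth.

## Known limitations

* Manual segmentation is assumed; there is no automated muscle detector.
* The capsule geometry cannot represent bulging or branching fibres.
* Uniform-basal vs scattered classification on 2-D projections relies on
  the side-consistency heuristic described above.
* The MWU floor of $10^{-4}$ makes extremely small p-values
  indistinguishable — intentional, to mirror the documented contract.
* Eclosion summaries assume h.min notation with minutes < 60; malformed
  rows are errors, not guesses.
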