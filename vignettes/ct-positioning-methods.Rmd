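---
title: "Automatic CT patient positioning from AP localizers: models and methods"
author: "ctcenterline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic CT patient positioning from AP localizers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcenterline)
```

## The problem

Vertical mis-centering — the distance between a patient's body centerline and
the CT gantry isocenter — is common in practice and costly: tube current
modulation estimates attenuation from the anterior–posterior (AP) localizer,
and a patient positioned off-isocenter is magnified or minified in that
projection, which biases dose modulation and degrades image quality.
`ctcenterline` implements a fully automatic positioning method: a
convolutional encoder–decoder network synthesizes a 3D body volume from the
single 2D AP localizer acquired before every scan, the body contour and
lungs are segmented on that volume, and the vertical midpoint of their
bounding boxes — the centerline — is compared with the gantry isocenter.

Four quantities summarize performance for a case, all in mm on an
anterior-positive axis where negative values place a centerline *below* the
gantry centre (lower table height):

* `BCAP = BCDL − BCGTH` — error of the automatic method: body centerline on
  the network-reconstructed volume minus the same measurement on the
  ground-truth axial volume;
* `BCMP = BCGTH − isocenter` — the manual mis-centering the technologist
  actually produced;
* `LCAP`, `LCMP` — the same pair measured from the joint bounding box of the
  two lungs, for organ-centred positioning.

Hospital CT archives cannot ship with a package, so every stage is exercised
against a parametric chest phantom simulator with analytic forward
projection and exact ground-truth centerlines. The simulator is first-class,
tested code: it defines the study conditions under which the pipeline's
claims are validated.

## The phantom population

A case is an ellipsoidal body (soft tissue), two air-density ellipsoidal
lungs strictly inside it, a curved couch below, and optionally a blanket
shell draped over the anterior half:

* **Diameters.** `D_AP ~ N(24.3, 3.6)` cm and `D_Lat ~ N(30.1, 5.3)` cm,
  truncated at ±3 SD with joint redraw, matching an adult chest-CT
  population. The two diameters are drawn *jointly* with correlation 0.8:
  chest AP and lateral diameters co-vary strongly in adults, and an
  uncorrelated draw would make body width a free variable that absorbs the
  magnification cue the method depends on (below).
* **Mis-centering.** The table-height offset is `N(+9.35, 14.94)` mm — the
  manual-positioning error distribution of a large clinical cohort. Under
  this default, `P(|offset| > 10 mm) ≈ 0.58`, reproducing the observed
  ~60% prevalence of mis-centering beyond 10 mm; the mean absolute offset
  is ≈ 14 mm, matching reported technologist performance.
* **Couch.** A 20 mm thick circular-arc cradle (radius 400 mm, half-width
  180 mm) whose top sits 18 mm below the posterior skin. The 18 mm
  stand-off models the mattress pad a patient actually lies on, and keeps
  the body–couch air gap resolvable at the coarsest grid the pipeline
  measures on (~6 mm AP pitch on reconstructed volumes); a smaller gap
  would weld body and couch into one connected component by pure
  discretization, which no segmentation rule could undo.
* **Intensities.** Fixed normalized levels: background 0.0, lung air 0.15,
  blanket 0.35, couch 0.55, soft tissue 0.70. Rendering is anti-aliased
  (linear partial-volume ramp across one voxel, first-order exact for
  region volumes) and snapped to a 1e-4 intensity grid, which makes 16-bit
  integer DICOM storage exactly lossless.
* **Blanket.** An 8 mm shell with an 8 mm air loft over the anterior body
  half. The loft reflects how blankets actually drape and keeps the shell a
  separate image component, which is precisely the situation in which 3D
  surface cameras fail and this method claims robustness.

What the simulator does *not* emulate: anatomical shape (shoulders, breast
tissue, arms), HU physics, noise and beam hardening, scanner-specific
localizer post-processing, respiratory motion. Passing tests therefore
demonstrate the geometric and statistical correctness of the pipeline and
the learnability of positioning from projection geometry — not clinical
performance on real patients.

## Why the localizer carries table height at all

A *parallel* AP projection is mathematically blind to the vertical position
of what it projects: shifting the patient up or down changes nothing along
the integration axis. The information enters only through the divergent
(fan-beam) geometry of a real scanner: with the source `SDD = 600` mm above
the isocenter, a structure at height `h` is laterally magnified by
`m = SDD / (SDD − h)`. `projectLocalizer()` defaults to the idealized
parallel mode; the experiment pipeline uses the divergent mode, which is
the physically honest one. Two cues result:

1. the couch has a *fixed physical width*, so its projected edge positions
   read out couch height directly, independent of patient size;
2. the body's own shadow is magnified, and because `D_AP` (readable from
   the peak attenuation) and `D_Lat` are strongly correlated, the residual
   width carries height information.

The test suite verifies that a plain ridge regression from the
preprocessed 48×32 localizer decodes the true offset on held-out phantoms,
so the cue is demonstrably present in the network's input; the question the
end-to-end test answers is whether the image-to-image network finds and
uses it under a realistic training budget.

## Pre-processing

The localizer and axial volume are cropped to the intersection of their
physical lateral/longitudinal extents using position metadata, min–max
normalized to [0, 1], and resized (separable linear interpolation,
pixel-centre aligned so physical extents are preserved) to fixed matrices —
144×64 (lateral × Z) and 184×144×64 (AP × lateral × Z) at full scale. The
retained mm extents are recorded per case and reconstruct the scanner-frame
grid of any prediction, so centerlines measured on predictions are directly
comparable with the ground truth and the isocenter. Min–max normalization
of a constant image is undefined; it returns zeros with a warning. Cohorts
are split 80/20 into training and test sets, stratified per scanner,
because localizer pixel statistics are vendor-specific and models are
per-scanner.

## The network

A U-Net-style 2D convolutional encoder–decoder over the (lateral, Z) plane
whose final layer emits one output channel per AP bin of the coronal
volume. This keeps the 2×2 stride of a 2D network meaningful while
producing a 3D output; permuting the output channels to the first axis
yields the axial volume. Each level is a double convolution block (3×3,
zero pad 1; the first conv strided 2 in the encoder), batch normalization
and ReLU; decoder levels upsample (nearest ×2) and concatenate the mirrored
encoder activation. Batch size is 1 with per-sample normalization
statistics, training runs under Adam with no augmentation and no schedule,
and everything (weight init, shuffling) is seeded and bit-reproducible.
Input sizes not divisible by `2^depth` are reflect-padded and the output
cropped back.

Three architecture choices deserve justification because the default U-Net
fails without them at small training budgets:

* **Coordinate channels.** The height cues are *absolute-position* features
  (where the couch edge falls in the image), but convolutions are
  translation-equivariant and can only sense absolute position weakly
  through padding effects. Two fixed channels holding the normalized
  lateral and longitudinal pixel coordinates are concatenated to the input.
* **Global-context head.** The table height is one global scalar per case,
  while the output head is local. The spatially pooled bottleneck feature
  vector is broadcast and concatenated to the head's input, giving a
  one-layer path from global features to the AP placement of output mass.
* **Sigmoid output.** Intensities live on plateaus (air, lung, couch,
  tissue); a saturating output makes crisp plateau predictions easy to
  express, and downstream thresholding depends on crispness.

Loss (MSE default, L1 available) and learning rate (1e-3 default) are
configurable; the full-scale protocol is 50 epochs. The desk-scale
experiment (`defaultRunConfig()`) uses a depth-3 model with 16 base
channels on 48×32 localizers with 64 AP output bins, 20 epochs at learning
rate 3e-3 — the rate chosen from training-loss behaviour at this small
budget, where the library default visibly underfits. An optional tail
weight average over the final epochs is available in `trainConfig()`; it
reduces terminal gradient noise but softens the sigmoid outputs, so the
experiment defaults leave it off.

## Centerline measurement

All thresholds act on the min–max normalized volume, making measurements
invariant to affine intensity rescaling.

1. **Body segmentation.** Threshold at 0.25; erode the mask once
   (6-neighbourhood) — this shreds porous reconstruction fuzz and breaks
   the thin partial-volume welds that attach a blanket or a blur-fused
   couch to the body; label 26-connected components; keep the largest
   component passing the region shape rules — lateral/vertical aspect
   ratio ≤ 4 (rejects the wide flat couch) and projected solidity ≥ 0.5
   (area over convex-hull area of the Z-projection; rejects thin curved
   shells such as blankets and the cradle). A component whose vertical
   occupancy profile still shows a couch-like waist (a valley with ≥1.5×
   higher occupancy on both sides) is split at the valley — the valley
   level stays with the body, since the true posterior skin sits inside
   the blurred gap — and re-evaluated; a clean body has a unimodal
   profile, so this is a no-op on ground truth. Two dilations intersected
   with the original mask then restore the exact pre-erosion boundary on a
   clean mask (and the typical blur depth of a reconstructed surface on a
   soft one); vertical levels at the extremes supported by fewer than 16
   voxels are trimmed, because bounding-box limits are max statistics and
   near-empty levels are fuzz; interior holes (the lungs) are filled.
2. **Lung segmentation.** Voxels inside the body below 0.45 (midway between
   normalized lung air ≈ 0.21 and soft tissue 1.0); the two largest
   components are the lungs, with a flagged single-component fallback. One
   *joint* bounding box covers both lungs.
3. **Bounding boxes and centerlines.** Axis-aligned boxes over mask voxels
   (outer voxel faces, mm); the centerline is exactly the vertical
   midpoint. An optional longitudinal scan range restricts the box —
   the centerline of a chest range differs from that of a cardiac range,
   which is why the measurement is defined on the cropped extent. Per-slice
   centerlines along Z are available for inspection.
4. **Truncation.** A body touching the lateral or vertical field-of-view
   border on more than 5% of its slices is flagged; such cases are excluded
   from experiments, mirroring the clinical exclusion of truncation
   artifacts (automated here).

The threshold 0.25 follows the phantom intensity ledger (between lung air
0.21 and couch 0.79 on the normalized scale, so lungs become interior holes
and the couch stays segmentable-but-removable). The lung threshold 0.45
sits midway between lung air and tissue; a value below 0.21 cannot see the
phantom's own lungs, so the margin is deliberately wide to stay robust on
soft reconstructed volumes.

## Metrics and statistics

`positioningErrors()` is exact arithmetic on two centerline reports sharing
a scanner frame. `cohortSummary()` reports mean, SD, a normal-approximation
95% CI (`mean ± 1.96·SD/√n`, matching the conventional presentation of
such tables; a bootstrap would add nothing at these n), median, IQR, the
fraction of cases strictly beyond 10 mm and the count beyond 20 mm.

The cohort comparisons use nonparametric tests implemented in the package
and cross-checked against independent oracles in the test suite:

* **Mann–Whitney** (automatic vs manual errors, signed and absolute): exact
  two-sided p by full enumeration of label assignments when the smaller
  sample has ≤ 8 observations, otherwise the normal approximation with tie
  and continuity correction.
* **Spearman** (body size — effective diameter `√(D_AP·D_Lat)` — vs
  absolute error): average ranks on ties, two-sided t-approximation p.
* **Kolmogorov–Smirnov normality** with estimated parameters
  (Lilliefors-style): the p value comes from a seeded Monte-Carlo null
  rather than the classical KS distribution, which would be anticonservative
  when mean and SD are estimated from the sample.

Significance is read at 0.05, with no multiplicity correction, matching the
protocol the metrics mirror.

## The experiment pipeline

`runExperiment()` chains simulate → preprocess → split → train → predict →
measure → evaluate under one master seed (stage seeds are derived offsets).
Ground truth and predictions go through the *same* centerline module.
Truncated cases are excluded before the split; exclusion counts are
reported. Per-case volumes are streamed, so memory does not grow with
cohort size; `persist = "all"` serializes every stage (NIfTI volumes, DICOM
scouts, checkpoint, reports) for stage-isolation work at small scales.
Deterministic re-runs reproduce reports bit-identically.

Desk-scale problem sizes, chosen so the full validation suite runs on one
CPU in minutes: 96×96×64 voxel phantoms at 4×4×6 mm, 250-case cohorts
(200 train / 50 test), 48×32 localizers, 64 AP output bins (≈ 6 mm
prediction pitch), depth-3 model, 20 epochs. The geometric oracle suite
checks 100 phantoms against the analytic centerlines at half the largest
voxel spacing; the end-to-end recovery experiment reports the median over
three seeds of the test-set mean |BCAP|.

## Numerical choices and edge cases

* Rendering uses a symmetric linear partial-volume ramp (first-order exact
  volumes); the suite checks voxelized region volumes against the analytic
  ellipsoid volume at the 1% level on the default grid.
* The divergent projector samples each vertical level with a per-level
  lateral scale `(SDD − y)/SDD` and linear interpolation; it converges to
  the parallel projector as SDD → ∞ (tested at SDD = 1e7).
* Resizing is pixel-centre aligned: mm coordinates survive crop → resize →
  inverse mapping within half an output pixel.
* Bounding-box limits are outer voxel faces; a degenerate single-voxel mask
  yields a box of one voxel spacing centred on that voxel.
* A constant image cannot be normalized; it yields zeros with a warning.
  An empty or shape-rule-failing segmentation raises "no body found" rather
  than guessing.
* Mann–Whitney enumeration is capped at 5e5 combinations; beyond that the
  normal approximation is used regardless of the exact threshold.

## Known limitations

* Ellipsoidal anatomy makes the body centerline independent of the scan
  range by symmetry; the scan-range machinery is exercised against the
  analytic oracle, but range-dependence as dramatic as in real anatomy
  does not arise in simulation.
* The network learns the magnification-based height cue reliably only when
  diameters are correlated and the couch edges are visible; on vendors
  whose localizers are heavily post-processed the cue may differ, which is
  one reason models are per-scanner.
* Lung centerlines on soft reconstructed volumes are noisier than body
  centerlines (the lung-air plateau is closest to the segmentation
  threshold), mirroring the clinical finding that lung centering is the
  harder task.
* The statistics module implements the tests the protocol uses; it is not
  a general-purpose statistics library.
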