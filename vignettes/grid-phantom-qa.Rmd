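---
title: "Measuring geometric distortion with a 3D grid phantom: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring geometric distortion with a 3D grid phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gridwarp)
```

## The measurement problem

MR images are geometrically distorted by main-field inhomogeneity and
gradient-coil nonlinearity. For applications that plan interventions on MR
images — stereotactic surgery and radiotherapy above all — the distortion of
a scanner must be measured periodically, and the measurement should be
automatic, vendor-neutral, and robust to the phantom's exact construction.

`gridwarp` measures distortion from volumetric images of a regular 3D grid
phantom: solid bars of thickness 3 mm whose crossings (vertices, 15 mm
apart) serve as control points (CPs). A CT acquisition of the same phantom
provides the geometric ground truth, since CT is free of the MR-specific
distortion mechanisms. Two independent routes produce a per-CP displacement
vector field:

1. **Template matching (reference route).** Each volume is scanned with a
   small binary template of a bar crossing (7.5 mm cube) using 3D
   zero-normalized cross-correlation; the thresholded correlation map's
   components yield CP locations, and MR CPs are paired with the closest CT
   CPs. The displacement is `detected − reference` per pair.
2. **Nonrigid registration (proposed route).** After a masked rigid
   pre-alignment restricted to a 27 mm sphere around the isocenter (where
   distortion is negligible) and resampling onto the reference grid, the
   reference volume is registered to the observed volume with a cubic
   B-spline free-form deformation optimized by multiresolution stochastic
   gradient descent. The recovered transform is applied to the reference
   CPs; no per-CP detection in the MR image is needed.

The displacement-magnitude distribution is summarized by its maximum, mean,
median and quartiles; the two routes are compared per statistic under a
half-pixel rule (differences below half the observed image's pixel size are
treated as non-significant); and a scanner is classified *high-performing*
when its maximum displacement is below 1 mm and *passing* the accreditation
bound when it is at most 2 mm (exactly 1.0 mm is not sub-millimetre; exactly
2.0 mm still passes).

## The synthetic validation study

No public phantom acquisitions accompany this problem, so validation is by
construction: `voxelize_phantom()` renders the grid into a reference
(CT-like: bright grid, dim background) and an observed (MR-like: dark grid
in a signal-producing oil background) volume, and `warp_volume()` distorts
the observed volume by an analytically known smooth vector field, inverted
per voxel by fixed-point iteration to below 0.01 mm residual, plus seeded
Gaussian intensity noise. `true_cp_positions()` then gives the exact
positions every route should recover.

The study conditions are fixed as follows and used throughout the tests and
the acceptance script:

* geometry: 15 mm vertex spacing, 3 mm bars; the full phantom extent
  (120 × 150 × 150 mm, 1089 vertices) for the identity check, and a
  90 × 90 × 90 mm grid (343 vertices, 216 cell midpoints) for the
  known-field studies so that several complete pipeline runs stay within a
  desktop time budget; unit tests use 30–60 mm grids;
* voxels: 1.0 mm isotropic for both modalities (the method is
  resolution-agnostic; sub-voxel behaviour is additionally exercised at
  0.5 mm in the localization tests);
* intensities: observed background 1000 / grid 50, reference background
  −100 / grid +120 — only the relative contrast matters;
* noise: additive Gaussian, σ = 20 for the observed volume (2 % of
  background, a typical phantom SNR) and σ = 5 for the reference;
* distortion fields: random second-order polynomial fields rescaled to a
  2 mm peak magnitude over the phantom domain (the scale of uncorrected
  head-coil distortions), evaluated against recovery RMSE ≤ 0.25 mm.

**What the generator does and does not emulate.** It reproduces the
geometry, contrast and noise level of grid-phantom acquisitions and smooth
system-type distortion fields. It does *not* emulate structured artifacts —
Gibbs ringing, intensity bias fields, susceptibility effects at the oil
interfaces, slice-profile effects. Two consequences matter for
interpretation: (1) i.i.d. Gaussian noise averages out over the fresh
per-iteration sample draws of the stochastic optimizer, so overfitting at
too-fine control lattices is *milder* here than with real scanner data;
(2) passing the synthetic suite demonstrates correctness of the machinery
and its sub-voxel accuracy under the stated conditions, not robustness to
every clinical artifact.

## Control-point localization choices

The correlation threshold (default 0.5) and minimum component size
(3 voxels) are configurable; an automatic mode picks the largest threshold
whose component count matches the expected vertex count when the geometry
is known.

Two localization details deviate from the plainest
threshold-and-center-of-mass reading and are worth recording:

* **Peak interpolation instead of blob center-of-mass.** The suprathreshold
  blob around a *boundary* vertex is asymmetric (template arms extend past
  the grid edge into background), which biases a correlation-weighted
  center of mass by 0.2–0.5 voxel systematically. Separable three-point
  parabolic interpolation of the correlation peak is unbiased to first
  order there (the missing-arm region is flat and contributes no gradient)
  and measured about half the displacement RMSE; it is the default
  (`localization = "peak"`), with weighted and binary COM retained as
  options. The parabola shift is clamped to ±1 voxel.
* **Ridge rejection.** Along a bar between vertices the template's matching
  arm produces an elongated suprathreshold *ridge* whose peak position
  within the ridge is noise-determined; such components are rejected by a
  bounding-box elongation test (axis ratio > 2.5) rather than localized.
  True vertex blobs are compact.

Manual verification in the original workflow is replaced by review flags:
components that look merged (3× the median size) or weak (peak within 0.1
of the threshold) are flagged in the exported CP table, never silently
corrected.

## Registration design

**Metric.** Mattes-style mutual information (32 histogram bins, box window
on the fixed axis, cubic B-spline Parzen window on the moving axis) is the
default, since reference and observed volumes have opposite contrast;
mean squares is selectable for same-contrast (e.g. CT–CT stability) runs.

**Transform and direction.** The transform maps reference coordinates to
observed coordinates, so it applies directly to reference CPs. The control
lattice at the finest level has spacing FGS (default 30 mm); each coarser
level doubles the spacing and halves the image resolution (Gaussian
smoothing with σ = factor/2 voxels before decimation). Between levels the
coefficient lattice is refined by exact dyadic B-spline subdivision
(weights 1/8, 6/8, 1/8 and 1/2, 1/2). The lattice is anchored at the volume
center and padded two control points beyond the mask bounding box; outside
the support the boundary cells' polynomial pieces extend the field
naturally, so CPs slightly outside the mask still map smoothly.

**Sampling and mask.** Each iteration draws NSS (default 3000) uniform
random positions inside the mask — by default a dilation (one bar
thickness) of the grid segmentation of the reference volume — with fresh
jitter every iteration. All draws derive from the run's seed, making
registrations bit-reproducible.

**Step control.** The optimizer is adaptive stochastic gradient descent
with three safeguards chosen after observing failure modes of the plain
`a/(A+t)` rule on sharp, noisy phantom images: (1) the step scale is
calibrated per level so the first update moves no control point by more
than half a voxel, and two independent calibration batches must agree in
direction (gradient cosine > 0.05) — on already-aligned images the
stochastic gradient is pure noise, the cosine is near zero, and the level
correctly does nothing; (2) a decay clock advances when successive
gradients anti-correlate (overshoot or noise) and rewinds when they agree;
(3) every update is clipped to half a voxel. Bending-energy regularization
is available (`bending_weight`) but defaults to 0.

**Parameter ranges and the sweep.** The four swept parameters keep their
conventional ranges — FGS 5–60 mm, resolutions 1–6, samples 1000–7000,
iterations 100–1000 — with defaults FGS = 30 mm, NR = 3, NSS = 3000,
MNI = 500, which the sequential coordinate-wise search
(`sequential_sweep()`: FGS first in an NR = 4 context, then NR, NSS, MNI,
then a final FGS re-sweep) reproduces as optimal on synthetic suites. Ties
break deterministically to the smaller value. Too-fine lattices (FGS below
the 15 mm vertex spacing) overfit: the error against detected CPs rises,
and the midpoint diagnostic — comparing transformed centers of 8-CP cells
against the mean of the detected corner CPs, where the oil background
carries no information — deteriorates first.

**Rigid stage.** Nelder–Mead over the 6 rigid parameters on a
coarse-to-fine smoothing schedule (σ = 4, 1.5, 0 mm): the unsmoothed
metric's capture range is only about a bar thickness, so smoothing first
widens the basin beyond realistic positioning errors (several mm and
degrees). The final stage uses up to 60 000 ROI voxels and 64 MI bins;
fewer samples or bins leave a histogram-noise floor of a few tenths of a
millimetre, which would otherwise dominate the whole pipeline's error on an
ideally aligned pair. Because distortion is assumed negligible only near
the isocenter, the ROI is a 27 mm sphere by default. A genuine
whole-phantom rigid component of the distortion field is absorbed here by
design; validation scoring therefore compares recovered displacements
against the field expressed in the rigidly-aligned frame.

## Numerical details and degenerate inputs

* Quantiles use linear interpolation between order statistics (R type 7),
  stated so cross-implementation comparisons match.
* NCC is computed only where the template fully fits; the margin is −1.
  Zero-variance templates and windows are rejected or scored 0.
* Voxelization labels a voxel as grid when its center lies within half a
  bar thickness (Chebyshev distance) of a bar segment extended half a
  thickness at its ends; bar faces that align exactly with voxel-center
  planes gain one tie-inclusion layer, which is why convergence checks
  sample voxel sizes in general position (e.g. 3/7 mm).
* The fixed-point warp inversion is guarded: fields must stay below half
  the vertex spacing (7.5 mm), and non-convergence after 50 iterations is
  an error.
* Empty suprathreshold sets, unmatched CPs, and failed acquisitions in a
  sweep are reported (warnings, review flags, exclusion lists), not fatal.

## Reproducibility

Every stage's randomness derives from one master seed; two runs with the
same seed produce byte-identical transforms, CP tables and reports (wall
times live only in the console log, not in artifacts). Each persisted
artifact embeds the seed and a hash of the scientific configuration —
output paths and data objects are excluded from the hash so the same
analysis written to two directories stays identical.

## Known limitations

* The synthetic study cannot certify robustness to structured MR artifacts
  (see the generator note above); the overfitting signature at FGS = 5 mm,
  while reproduced, is weaker than with real data.
* The container trim rule is a modelling choice (keep a vertex when its
  whole bar cross-section fits inside the cylinder); manifests record the
  realized vertex count rather than forcing a particular one.
* Rigid pre-alignment assumes the phantom is roughly centred (within the
  capture range of the smoothed stage, several mm/degrees) and that
  distortion within 27 mm of the isocenter is negligible.
* Volumes must share an axis-aligned world frame; oblique acquisitions
  should be resampled upstream.
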