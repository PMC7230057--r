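# gridwarp

Interaction-free measurement of geometric distortion in volumetric scanner
images (MRI foremost) using a 3D grid phantom and a geometric-reference CT
acquisition.

MR images are spatially warped by main-field inhomogeneity and gradient
nonlinearity; surgical and radiotherapy planning need that warp quantified
per scanner. `gridwarp` computes per-control-point displacement vectors
**d(v) = v′ − v** for the vertices *v* of a regular grid phantom (15 mm
spacing, 3 mm bars) by two independent routes:

* **template matching** — 3D zero-normalized cross-correlation of a binary
  vertex template over each volume, thresholding + component analysis +
  sub-voxel peak localization, then mutual nearest-neighbour pairing of MR
  and CT control points;
* **nonrigid registration** — masked rigid pre-alignment in a 27 mm sphere
  around the isocenter, then multiresolution stochastic-gradient B-spline
  free-form registration (mutual-information metric; final control-grid
  spacing FGS = 30 mm, 3 resolutions, 3000 samples/iteration, 500
  iterations by default) whose transform is applied to the reference
  control points.

Displacement magnitudes |d| are summarized as max / mean / median / Q1 / Q3,
compared between routes under a half-pixel non-significance rule, plotted
against distance from the isocenter, and classified: max < 1 mm is
high-performing, max ≤ 2 mm passes the accreditation bound.

A synthetic-phantom module generates reference (CT-like) and observed
(MR-like) volumes warped by analytically known smooth fields (≤ 2 mm, plus
Gaussian noise), giving the package a fully self-contained validation path
with exact ground truth.

## Worked example

```r
library(gridwarp)

# phantom geometry and one synthetic acquisition with a known 2 mm field
g   <- build_grid_geometry(vertex_spacing = 15, bar_thickness = 3,
                           grid_extent = c(90, 90, 90))
fld <- random_smooth_field(max_magnitude = 2, domain_radius = 78, seed = 101)
sim <- simulate_acquisition(g, fld, voxel_spacing = 1, seed = 43)

config <- qa_config(sim$reference, list(acq = sim$observed), g, seed = 7)
report <- run_qa(config)
report
#> <qa_report> 1 acquisition(s), config 8e87b2b7, seed 7
#>   acq: TM max 1.867 / mean 0.530 mm; registration max 1.808 / mean 0.547 mm; within ACR limit

a <- report$acquisitions$acq
a$comparison
#> <method_comparison> half-pixel = 0.500 mm
#>   max    +0.0598 mm
#>   mean   -0.0177 mm
#>   median -0.0324 mm
#>   q1     -0.0362 mm
#>   q3     +0.0199 mm
```

Reading: both routes see a maximum distortion of ~1.8 mm (the injected
field peaks at 2.0 mm at the domain edge, outside the outermost vertex), so
the acquisition exceeds the 1 mm high-performance bound but stays within
the ±2 mm accreditation limit; every summary statistic differs between the
routes by far less than half a voxel (0.5 mm), so the interaction-free
registration route reproduces the template-matching reference.

`run_validation_study()` additionally scores both routes against the
analytic truth — for the acquisition above it prints

```
#>   field1: TM RMSE 0.116 mm, registration RMSE 0.071 mm (true max 2.00 mm)
```

— and `sequential_sweep()` reproduces the coordinate-wise
registration-parameter search (FGS → NR → NSS → MNI, then FGS again).

A thin CLI wraps the same functions:

```sh
gridwarp simulate --spacing 15 --bar 3 --extent 120x150x150 --voxel 1 \
         --distortion random:2.0:7 --seed 7 --out ./sim/
gridwarp qa --reference ./sim/reference.nii.gz --observed ./sim/observed.nii.gz \
         --spacing 15 --bar 3 --extent 120x150x150 --seed 1 --out ./qa/
```

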