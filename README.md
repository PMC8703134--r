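# chromaxial

Post hoc correction of depth-dependent axial chromatic aberration in
multi-channel volumetric confocal images.

## The problem

Multicolor confocal imaging of cleared tissue (SeeDB2-class agents, deep
stacks of millimetre scale) suffers from chromatic aberration: each
excitation wavelength focuses at a slightly different depth, so the same
structure appears at different z positions in different channels. The
lateral component is typically small (< 1 μm) and ignorable; the axial
component can reach 15–20 μm and, crucially, varies with imaging depth.
Uncorrected, it breaks co-localisation of multicolor-labeled neurites in
exactly the deep volumes that clearing makes accessible.

`chromaxial` implements a simple, instrument-agnostic correction. For each
non-reference channel the axial shift is modeled as a linear function of
depth,

    Δz(d) = a · d + b,

estimated from intensity-weighted centroids of multi-fluorophore
calibration beads — or of "guide stars", bright isolated structures inside
the biological sample itself. Each object's centroid is the thresholded
center of mass

    c = Σ I(v) · pos(v) / Σ I(v)

over voxels brighter than mean + 10·SD of the (z-median-filtered) ROI, and
the depth covariate is the reference-channel centroid z. The fit's quality
feeds a power analysis: with Cohen's effect size f² = r²/(1 − r²), the
achieved power of the regression's F-test is computed from the noncentral F
distribution (df1 = 1, df2 = n − 2, noncentrality λ = f²·n), and a model
whose power falls below 0.7 is refused for correction. Correction itself is
frame reassignment: each target-channel frame at stage position z holds
content from reference depth z_c = (z − b)/(1 + a), and every reference
frame is rebuilt from the target frame whose corrected position is nearest
— duplicating or deleting frames as needed, never resampling intensities.

A synthetic phantom module renders bead slabs and guide-star volumes with
known injected aberration, so the entire pipeline is testable against exact
ground truth without microscope data.

## Worked example

Calibrate on a synthetic 2 mm-deep two-channel bead slab with a known
injected shift law Δz(d) = 0.004·d − 18 μm and per-bead jitter of 0.5 μm,
then correct it:

```r
library(chromaxial)

spec <- phantom_spec(shape = c(500L, 64L, 64L), pitch = c(4, 2, 2),
                     n_objects = 50, seed = 1)
phantom <- generate_phantom(spec)
phantom$stack
#> MultiChannelStack: 2 channel(s) [473, 559], reference '473', 500 x 64 x 64 (z,y,x)

samples <- measure_batch(phantom$stack, phantom$rois)
head(samples[samples$channel == "559", c("label", "depth_um", "dz_um")], 4)
#>     label  depth_um      dz_um
#> 2 obj_001  549.8569 -15.933019
#> 4 obj_002 1778.1141  -8.729789
#> 6 obj_003 1848.0671 -10.038183
#> 8 obj_004  160.0418 -17.553070

model <- build_model(samples, ref = "473")
model
#> CalibrationModel (reference '473', 1 target channel(s)):
#> AxialRegression 473 -> 559: dz = 0.00406166 * depth + -18 um  (n = 50, r2 = 0.9037, f2 = 9.379, power = 1)

corrected <- apply_correction(phantom$stack, model)
after <- measure_batch(corrected$stack, phantom$rois)
summary(abs(after$dz_um[after$channel == "559"]))
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#> 0.02867 0.27438 0.76105 0.90125 1.10526 3.52838
```

The fitted slope and intercept recover the injected law (0.00406 vs 0.004;
−18.0 vs −18), and correction shrinks a 10–18 μm channel offset to the
half-frame scale (dz/2 = 2 μm; the residual tail reflects the 0.5 μm
per-bead jitter plus centroid localisation error). `measure_batch()` works
identically for guide-star ROIs (`source = "guide_star"`), and
`regression_power()` / `required_n()` answer "how many guide stars are
enough": for the weakest published guide-star fit (r² = 0.757), 7 give
power ≈ 0.96 and 10 give ≈ 0.998.

Real acquisitions enter through `read_stack()` (multi-page TIFF plus a YAML
sidecar carrying voxel pitch, channel wavelengths, reference channel and z
orientation) and `read_rois()` (CSV or ImageJ rectangle `.roi`/`.zip`);
`run_pipeline()` and the thin `inst/scripts/chromaxial` front-end wire the
steps `simulate → detect → measure → fit → power → correct` over plain
files.

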