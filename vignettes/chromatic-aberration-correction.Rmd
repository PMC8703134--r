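---
title: "Depth-dependent axial chromatic aberration: measurement, power analysis and frame-reassignment correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-dependent axial chromatic aberration: measurement, power analysis and frame-reassignment correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromaxial)
```

## The model

In a multicolor confocal z-stack, an object at reference-channel depth $d$
(the stage position at which the reference laser images it) appears in a
second channel at stage position

$$z_{\mathrm{target}}(d) = d + \Delta z(d), \qquad \Delta z(d) = a\,d + b ,$$

where $b$ (μm) is the depth-independent axial chromatic offset between the
two excitation wavelengths and $a$ (μm of shift per μm of depth,
dimensionless) captures the depth dependence introduced by refractive-index
mismatch accumulating along the optical path. The model is deliberately
linear: across 0.3–2 mm of cleared tissue the measured shift-versus-depth
relations are well fitted by straight lines, and a linear law is the only
one that can be estimated reliably from the 10–100 calibration objects a
user can realistically measure. Lateral shifts are measured and summarised
but never corrected — they are typically below one voxel pitch, and the
correction here is axial-only by design.

All shifts are expressed relative to one **reference channel**; any laser
can serve as reference, and for noiseless linear data slopes compose
transitively across reference choices (verified in the test suite to first
order in $a$).

## Centroid measurement

Each calibration object — a multi-fluorophore bead or an in-sample "guide
star" — is localised per channel by a thresholded center of mass inside a
user-supplied or auto-detected rectangular ROI:

1. a length-3 median filter along z removes shot-noise spikes from each
   (y, x) column (nearest-neighbour padding at the ends);
2. voxels brighter than $m + k\sigma$ of the filtered ROI ($k = 10$ by
   default) are kept;
3. the centroid is the intensity-weighted mean voxel position, converted to
   physical μm (a voxel at 0-based index $(n, j, i)$ sits at
   $(z_0 + n\,\Delta z_{\mathrm{pitch}},\; j\,dy,\; i\,dx)$).

Filtering *before* computing the threshold statistics is intentional: a
shot-noise spike inside the ROI would otherwise inflate the standard
deviation and raise the cut. The opposite order is available as
`threshold_before_filter = TRUE` for comparison. Statistics are ROI-local;
a generously traced ROI (ample dark surround) therefore gives a lower,
better-behaved threshold than a box hugging the object — the phantom
module's auto-generated ROIs pad to 6σ for exactly this reason.

For dim guide stars the 10 SD cut can exclude everything; the threshold
multiplier is then halved (with a message and a `fallback_threshold` flag)
until a voxel passes or $k < 1$, at which point the ROI is declared empty.
A guide star must span its full z extent inside the ROI; if more than 1% of
above-threshold mass sits in the first or last ROI frame the sample is
flagged `possibly_truncated`.

The object's **depth covariate is the reference-channel centroid z**, never
the ROI's geometric middle: the ROI is an arbitrary user tracing, the
centroid is not.

## Power analysis

Whether enough objects were measured is decided from the fit itself. With
coefficient of determination $r^2$, Cohen's effect size is
$f^2 = r^2/(1-r^2)$, and the achieved power of the single-predictor
F-test ($H_0$: the regression explains no variance) is

$$\mathrm{power} = P\!\left(F'_{1,\,n-2,\,\lambda} > F_{1-\alpha;\,1,\,n-2}\right),
\qquad \lambda = f^2 n ,$$

the fixed-model "R² deviation from zero" convention of standard power
software. `required_n()` inverts this by exhaustive scan (power is strictly
increasing in $n$). Defaults: $\alpha = 0.05$; a regression with achieved
power below **0.7** is flagged insufficient and `apply_correction()`
refuses it unless forced. For the weakest guide-star fit we reproduce
($r^2 = 0.757$, $f^2 = 3.115$), 7 objects give power 0.957 and 10 give
0.998; the smallest n reaching 0.99 is 9. Noiseless synthetic data reach
$r^2 = 1$; this is flagged `degenerate_fit` with $f^2 = \infty$ and power
1 rather than treated as an error.

The analytic power is cross-checked in the tests against 100 000
Monte-Carlo regressions on a fixed design scaled so the true noncentrality
is exactly $f^2 n$ (agreement within 0.005).

## Correction by frame reassignment

A target-channel frame acquired at stage position $z$ holds content from
reference depth

$$z_c = \frac{z - b}{1 + a},$$

the exact inverse of the measured relation (the first-order variant
$z - (az + b)$ differs by $O(a^2 z)$, negligible at realistic slopes, and
is kept behind a flag only for comparison). Each reference frame $n$ is
then rebuilt from the target frame whose corrected position is nearest to
the reference position — ties broken toward the smaller index, out-of-range
positions clamped to the nearest existing frame and flagged as
extrapolated. Some target frames are duplicated, others deleted; counts are
reported. X–y content is untouched and output dimensions always equal input
dimensions.

Nearest-frame reassignment (rather than linear interpolation along z) is a
deliberate choice: it never alters intensity statistics, which downstream
quantification may depend on. Interpolation support was considered and
rejected as a default for that reason.

## The phantom generator

`generate_phantom()` renders the calibration experiment the package is
designed for: a slab of multi-fluorophore beads in a deep volume, imaged in
two or more channels whose axial positions follow a known linear law plus
per-bead jitter $\varepsilon \sim N(0, \sigma_\varepsilon^2)$. Defaults
describe the target acquisition — 2 μm isotropic voxels over a
2 mm × 512 μm × 512 μm volume, 4 μm beads (Gaussian σ = 2 μm lateral,
×3 axial elongation mimicking the confocal PSF), peak 10 000 counts over a
100-count background with 50-count read noise, 50 beads, channels
"473"/"559" with $\Delta z(d) = 0.004\,d - 18$ μm and
$\sigma_\varepsilon = 0.5$ μm. Gaussian beads are used instead of hard
spheres because their sub-voxel truth position is exact and centroid
arithmetic is identical. `generate_guide_star_phantom()` renders short
capsules (neurite-like tubes) whose depths are drawn only from the top and
bottom thirds of the usable z range — the two-cluster design that anchors a
linear regression.

The truth table records every bead's reference position, exact per-channel
shifts and the individual jitter realisations, so tests can separate fit
error from model error. Identical spec + seed gives bit-identical output.

What the phantom does **not** emulate: diffraction PSFs, depth-dependent
attenuation and blur, refractive-index-mismatch physics, non-linear shift
laws, spatially varying (x–y) aberration, and autofluorescent background
structure. Passing tests therefore demonstrate the correctness of the
measurement/fit/correction machinery under the stated model, not robustness
to every property of real acquisitions.

## Numerical choices and degenerate inputs

* ROIs are 0-based and half-open on every axis; ImageJ rectangles are
  converted on read (`x_min = left`, `x_max = left + width`). This removes
  the off-by-one ambiguity that plagues pixel-box conventions.
* Whether "deeper into the sample" is +z or −z differs between upright and
  inverted stands; it is carried as an explicit `z_orientation` metadata
  flag, never assumed.
* Voxel pitch must come from the sidecar config; a missing pitch is an
  error, never silently defaulted.
* Bead auto-detection thresholds at whole-stack mean + 10 SD (scale-free:
  invariant to positive affine intensity rescaling), labels 26-connected
  components in 3D, and rejects components outside configurable size
  bounds, boxes that touch the volume border after padding (a truncated
  bead biases its centroid) and boxes overlapping another component (one
  object per ROI). The threshold and size bounds are engineering defaults
  and remain configurable; detection runs on the reference channel only,
  with boxes shared across channels, so the detection `margin` must exceed
  the largest expected shift in voxels.
* `|1 + a| < 10^{-6}` is a degenerate model (the corrected-position map
  loses monotonicity) and is refused.
* Constant-response fits (reference regressed on itself) return slope and
  intercept exactly 0 with a `constant_response` flag instead of a
  divide-by-zero r².

## Localisation precision and its consequences

The thresholded center of mass localises a well-sampled bead to roughly
0.1–0.2 voxel per channel. The error is dominated not by noise but by the
discrete truncation boundary of the threshold set: voxels near the
$m + k\sigma$ cut enter or leave the kept set depending on the sub-voxel
phase of the object, contributing an asymmetry proportional to the
threshold level. It shrinks with a lower threshold (larger ROIs, lower
$k$) but has no zero limit on a discrete grid. Consequently:

* measured inter-channel shifts carry ~0.2–0.5 voxel of scatter on top of
  any true per-object jitter — the regression absorbs this as residual
  variance, and fitted slopes/intercepts remain unbiased (verified by CI
  coverage over repeated phantoms);
* after a perfect correction the re-measured residual shift is bounded by
  the half-frame quantisation dz/2 **plus** the re-measurement error of
  both channels. The correction machinery itself achieves the half-frame
  optimum (the frame map equals the exhaustive nearest-position
  assignment), but a residual measured through the same centroid pipeline
  can exceed dz/2 by a few tenths of a voxel for beads whose rounding
  residual lands near the half-frame boundary.

## Problem sizes used by the tests

The full-scale default phantom (1000 × 256 × 256 voxels) describes the real
acquisition; the test-suite and the reproduction script exercise the same
physics on laterally cropped grids — typically 500 × 64 × 64 voxels at
(4, 2, 2) μm pitch, 15–50 beads, and 20 repeated seeds for coverage checks
— which the package treats as its standard desk-scale verification
configuration. All quantitative checks (parameter recovery within 3
standard errors, CI coverage, Monte-Carlo power agreement within 0.005,
assignment-oracle identity) are independent of this cropping.

## Known limitations

* The shift law is linear in depth; strongly non-linear aberration (e.g.
  collar badly mismatched to the immersion medium) needs a richer model.
* Correction granularity is one frame; sub-frame alignment would require
  interpolation, with the intensity-statistics caveat above.
* Lateral chromatic aberration is reported but not corrected.
* Stacks are held in memory (double precision); desk-scale volumes of a
  few hundred million voxels are the practical ceiling.
* Proprietary container formats (.oib, .lif) are out of scope — convert to
  TIFF and describe the acquisition in the YAML sidecar.
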