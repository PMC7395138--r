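---
title: "Measuring expansion factor, distortion and nanoscale morphometry with exmetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring expansion factor, distortion and nanoscale morphometry with exmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(exmetry)
```

## Scope and model

`exmetry` quantifies how faithfully an expansion-microscopy (ExM)
experiment magnifies a specimen. The physical model underlying all of it
is a coordinate map from pre-expansion specimen coordinates `x` (nm) to
post-expansion coordinates

\[ x \mapsto s\,M\,x + u(x), \]

where `s > 0` is the global linear expansion factor, `M` is a unimodular
(det = 1) matrix capturing anisotropic stretch/shear from sample
handling, and `u` is a smooth residual displacement field — the local
expansion inhomogeneity. The package estimates each piece from image
pairs and, independently, simulates the whole process with known
parameters so every estimator can be validated against ground truth.

## The synthetic phantom generator

`make_scene()` builds vector geometry (not images) for five specimen
classes: nuclei (filled ellipses, semi-major 4–6 µm), microtubule-like
filaments (smooth random curves, 25 nm wide), mitochondria (elongated
ellipses, optionally with internal cristae striping at a set spacing),
Golgi stacks (parallel ribbons at a set inter-cisternal spacing) and
centrioles (annuli in axial view, hollow barrels in lateral view). All
structural parameters are recorded as ground truth. Defaults: a
51.2 µm field imaged at 100 nm/px (512²), chosen as a typical confocal
field of view of a cell monolayer; organelle-scale scenes use smaller
fields (2–6 µm) so the expanded specimen still fits a 500² image.

`render()` rasterises the primitives by conservative bilinear splatting
of dense sample points (each primitive's `intensity` is its total
integrated signal), convolves with a Gaussian PSF (kernel normalised to
sum 1; default sigma 150 nm, a confocal-like value), adds a constant
background, scales everything by exposure time relative to a 100 ms
reference, and finally applies Poisson shot noise followed by additive
Gaussian read noise — in that physical order. With noise disabled, the
rendered total above background equals the scene's summed intensity up
to boundary truncation, a property the tests assert at 0.5%.

`deform_scene()` maps the *vector* sample points through
`x -> s M x + u(x)` and re-renders; no image-space warping is involved,
so the ground truth is interpolation-free. `u` is a band-limited
Gaussian random field: 32 seeded cosine components per vector component
with wavenumbers drawn inside the disk `|k| <= 2*pi/L` (`L` the
correlation length), affinely rescaled so the RMS magnitude over the
pre-expansion grid equals the requested amplitude exactly. The field is
a closure evaluable at any continuous point, which is what makes the
ground-truth distortion curves exact. One deliberate physical
consequence of intensity conservation: expanding a scene `s`-fold
dilutes signal per unit area by `s²`, so bright post-expansion phantoms
(e.g. the organelle morphometry scenes) set higher staining densities,
standing in for the longer exposures a microscopist would use.

Simulated defaults are conditions, not dials: the registration and
morphometry tests run at the expansion scales the package targets
(~15–17×), with the noise model on.

### What the phantoms do not emulate

No optical sectioning or 3D PSF (the registration pipeline operates on
2D maximum projections, as the measurement procedure prescribes), no
depth-dependent aberrations, no gel autofluorescence, no spectral
bleedthrough beyond a constant mixing fraction, and no biological
variability in organelle ultrastructure. Passing tests therefore show
that the *estimators* are correct and well-calibrated on images with
realistic PSF and noise — not that any particular biological sample
will behave this way.

## Registration

The distortion measurement needs the post-expansion image expressed in
the pre-expansion frame. `fit_linear()` estimates a similarity
(uniform scale, rotation, translation) or affine transform by
minimising the mean squared difference of z-normalised intensities over
a 3-level multiresolution pyramid. Initialisation is from intensity
moments: above-Otsu-threshold weighted centroid, second-moment scale
`(det C_post / det C_pre)^{1/4}` and principal-axis orientation, with a
coarse deterministic sweep of candidate rotations scored at the
coarsest scale (principal axes are unstable for isotropic content).
The optimiser is BFGS; there is no stochastic sampling anywhere, so
registration is fully deterministic. The physical expansion factor is
the pixel-frame scale times the pixel-size ratio of the two images.

`fit_bspline()` then fits a cubic B-spline free-form deformation
(control spacing 32 px at full resolution, the same control grid
optimised coarse-to-fine over the pyramid) by L-BFGS-B with analytic
gradients of the data term and of a discrete bending-energy penalty
(squared second differences of the control displacements). Two
properties matter for the science:

* the bending energy vanishes on affine fields, so residual linear
  mismatch left by the similarity stage (e.g. true shear) is *absorbed
  into the measured field* rather than suppressed — exactly what lets
  the similarity-vs-affine comparison attribute distortion to
  anisotropic handling;
* the penalty weight is expressed relative to the control-grid scale,
  so its absolute value is implementation-specific. The defaults
  (1e-1 for dense blob-like content such as nuclei, 1e-2 for
  filamentous content) were calibrated on phantoms: at 1e-2 the
  measured field of an undistorted 15.6× pair contributes < 0.15%
  relative error, while an imposed smooth 3% distortion is still
  recovered within ~20%. Raising the penalty monotonically shrinks the
  field to zero (a property test).

Interpolation is bilinear for both the metric and final resampling,
with image gradients precomputed by central differences; on PSF-smoothed
images this is accurate and fast. Out-of-domain samples are filled with
zero and excluded from the metric.

One practical subtlety: the pre-expansion image is diffraction-limited
on the unexpanded specimen (~150 nm PSF), while the post-expansion image
— after dividing the optics by the expansion factor — is effectively
much sharper, and the standard 2 px preprocessing blur of the post
image does not fully compensate. `distortion_report()` therefore also
blurs the pre image (default 1.5 px), bringing both channels to a
comparable effective resolution of ~200 nm in specimen units. Without
this, the non-rigid stage spends its freedom matching apparent
structure widths and lengths, which contaminates short-range distances
by a few percent.

## Distortion metrology

`extract_points()` binarises the preprocessed pre image (Otsu default)
and takes either the one-pixel boundary of the foreground (nucleus
images) or its Zhang–Suen skeleton (filamentous images).
`displace_points()` applies the measured field with bilinear
interpolation, and `rms_vs_length()` computes, for every unordered pair
(optionally a seeded uniform subsample above `max_pairs = 2e6`; an
all-pairs brute force is the test oracle and they agree to 1e-12), the
error `|d_def − d_i|`, binned by the pre-expansion distance `d_i` in
0.5 µm bins from zero (pairs below one pixel are dropped). Per bin the
default statistic is the mean of the absolute errors with its sd and
pair count; a true within-bin RMS is available via
`aggregator = "rms"`. Relative error divides the per-bin mean by the
bin-center length, and curves are reported in pre-expansion units, so
"2.5% at 10 µm" means 250 nm of error over a 10 µm biological distance.
Structure-class presets fix the point mode and the maximum measurement
length: outlines to 20 µm for nuclei, skeletons to 10 µm for
mitochondria and 8 µm for microtubules.

### Ground-truth closure

For simulated pairs the package computes the *true* distortion curve
without any registration: the exact map is evaluated at the point set,
the best-fitting linear transform (closed-form Procrustes for
similarity, least squares for affine; `fit_point_linear()`) is removed,
and the residual-displaced points (`residual_points()`) are fed to the
same `rms_vs_length()`. Removing the *best-fit* linear part — rather
than the nominal `s·M` — matters: a smooth random field with a long
correlation length contains a linear component over the field of view,
and both the real pipeline and any fair ground truth absorb it into the
linear registration stage.

The validation conditions use a 20 µm correlation length, i.e.
distortion that varies smoothly across the cell-scale field, as gel
inhomogeneity does; a B-spline grid at 3.2 µm resolves it comfortably.
Distortion at scales below the control-grid spacing is invisible to
*any* free-form-deformation metrology, this one and the original
procedure alike — a stated limitation, not a removable one.

## Expansion factor

Two estimators: `nuclear_areas()` + `expansion_factor()` (Otsu
threshold, hole filling, connected components, border-touching
components excluded to avoid truncation bias, minimum area 20 µm²
pre-expansion-equivalent to reject debris; factor =
`sqrt(mean(post)/mean(pre))` with means, matching the average-area
definition) and `crop_factor()` for landmark crops. On phantoms the
segmentation path recovers a 15.6× expansion within ±0.5, and agrees
with the registration-derived scale within 3% (a property test). The
per-object dispersion reported alongside the factor is the sd of
`sqrt(area_i / mean(pre))` over post-expansion nuclei — a transparency
measure, not the between-experiment sd a multi-sample study would
report.

## Morphometry

`thick_line_profile()` samples a band of configurable thickness
(10 px for organelle spacings, 5 px for centrioles, following the
measurement convention) with bilinear interpolation, averaging across
the band. `peak_spacing()` detects local maxima by prominence (default
10% of the profile's dynamic range, minimum separation 3 samples) after
an optional symmetric Gaussian smoothing of the profile (default sd 1
sample; it cannot shift a symmetric peak but stabilises the apex on
noisy, flat-topped ridges such as centriole walls), refines apex
positions by parabolic interpolation, and divides spacings by the
expansion factor — the correction is exactly linear in `1/factor`.
`roundness()` uses the fitted-ellipse convention: an ellipse with the
region's area and second-moment aspect ratio, giving
`4·area/(π·major²) = minor/major`; a circle and any moment-isotropic
shape (e.g. a filled square) score 1, and the value is invariant to
rotation and uniform scaling. Pixel-perimeter circularity is available
but discouraged for small objects. Profiles are drawn from supplied
endpoint coordinates; automated organelle detection is out of scope by
design, mirroring the manual profile placement of the original
procedure.

## Signal quantification

`total_signal()` implements the three normalisations of the retention
and labeling-efficiency assays: per cell (field total over cell count),
per ROI (mean background-corrected signal times ROI area) and per mask
area (ROI total over the area of a structure mask), always
background-corrected pixelwise first and divided by the exposure time.
Rendered phantom fields with equal per-cell signal but different cell
counts and exposures give normalised signals equal within 2% (an
acceptance property). `count_nuclei()` labels thresholded components
with an optional watershed split of touching nuclei — an algorithmic
stand-in for the manual merge correction, with no claim of equivalence.
`bleedthrough_subtract()` removes a constant fraction of a contaminating
channel, clipping at zero since intensities are non-negative.
`compare_groups()` is the classical unpaired two-tailed t-test, pooled
variance by default to match the referenced analysis software, Welch
optional.

## Numerical choices and degenerate inputs

* Coordinates are 0-based with pixel centers at integers, x along
  columns, y along rows; physical position = index × pixel size.
* Otsu thresholds are computed on each image's own range (256 levels);
  constant images are rejected, never silently thresholded.
* Registration on featureless (constant) images errors out; masks must
  match shapes exactly; profile endpoints must lie inside the image;
  empty point sets, empty ROIs, zero-area masks and non-positive areas
  are all named errors.
* Pair subsampling uses a seeded uniform draw of condensed pair
  indices; determinism is bitwise given the seed. All pipeline
  randomness derives from one top-level seed via hashed substreams, and
  every artifact embeds the configuration hash and seed.
* TIFF output is 32-bit float with a JSON sidecar carrying the pixel
  size and intensity scale (the linked TIFF writer does not persist
  resolution tags); reading honours standard resolution tags and
  ImageJ-style descriptions, and a file with no calibration at all is
  an error unless the caller supplies the pixel size explicitly.

## Problem sizes used in validation

The registration-based validations run on 512² pre images (51.2 µm at
100 nm/px) against ~500² post images, with 3 pyramid levels, a 32 px
control grid and up to 3000 skeleton/outline points (2×10⁶ pair cap) —
sizes at which a full similarity + B-spline chain takes on the order of
a minute. Morphometry and retention validations use 500–600² organelle
fields. These are the package's validation conditions; all sizes are
configurable.

## Known limitations

* 2D only; stacks are maximum-projected before registration.
* The B-spline metrology cannot see distortion below its control-grid
  scale (3.2 µm at defaults), and with the default penalty it
  under-reports the amplitude of recoverable smooth distortion by
  roughly 15% — within the package's validated tolerance, but a bias to
  keep in mind when comparing absolute distortion levels between
  protocols.
* The similarity/affine stage is intensity-driven; its absorbed linear
  component can differ from the point-set-optimal linear transform by a
  fraction of a percent, which propagates into the long-length end of
  the distortion curve.
* Segmentation-based expansion factors inherit threshold bias: the
  Otsu boundary sits slightly differently on pre- and post-expansion
  nuclei because the effective PSF (in specimen units) differs; on
  phantoms this stays within the quoted ±0.5.
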