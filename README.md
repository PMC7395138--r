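# exmetry

Validation analytics for expansion microscopy (ExM).

Iterative expansion protocols physically magnify a specimen ~13–21× in a
swellable hydrogel before imaging. Whether the numbers such an experiment
reports can be trusted hinges on a handful of quantitative checks:

* **Expansion factor** — the linear magnification, estimated as
  `sqrt(mean(post areas) / mean(pre areas))` from segmented nuclear
  cross-sections, or from landmark crops of registered image pairs.
* **Expansion homogeneity (distortion)** — register the post-expansion
  image to its pre-expansion counterpart with a similarity (or affine)
  transform, then with a cubic B-spline free-form deformation; apply the
  residual deformation field `u(p)` to outline/skeleton points of the pre
  image and summarise, for every point pair, the error
  `|d_def − d_i|` (with `d_i` the pre-expansion pair distance and `d_def`
  the distance after displacement) binned by measurement length — the
  RMS-error-versus-length curve.
* **Morphometry** — peak-to-peak spacings from thick line profiles
  (mitochondrial cristae, Golgi cisternae), Euclidean crest-to-crest
  tubule diameters, centriole roundness (`4·area/(π·major²)` of the
  fitted ellipse) and length-to-width ratios, all divided by the
  expansion factor to biological units.
* **Signal retention** — background-corrected total fluorescence,
  normalised per cell / per ROI / per mask area and per exposure time,
  compared across conditions with an unpaired two-tailed t-test.

Because raw ExM microscopy of this kind is rarely deposited, `exmetry`
ships a first-class **synthetic phantom generator**: vector scenes of
nuclei, microtubule filaments, mitochondria (with cristae), Golgi stacks
and centrioles are imaged through a Gaussian PSF with Poisson–Gaussian
noise, then re-imaged after a known deformation
`x → s·M·x + u(x)` (global scale × unimodular shear × smooth band-limited
random field). Every estimator in the package can therefore be checked
against exact ground truth.

## Worked example

Simulate a 15.6× expansion of a mitochondria field and measure it back:

```r
library(exmetry)

scene <- make_scene("mitochondria", seed = 5)
pre   <- render(scene, imaging_params(), seed = 1)            # 100 nm/px
sim   <- deform_scene(scene, deformation_spec(scale = 15.6),
                      imaging_params(pixel_size_nm = 1600), seed = 2)

rep <- distortion_report(pre, sim$post, "mitochondria",
                         transforms = "similarity")
rep$similarity$expansion_factor
#> [1] 15.5997
rep$similarity$curve
#> <rms_curve> 20 bins, 0.25-9.75 um, mean relative error 0.078%
plot(rep$similarity$curve)
```

The fitted similarity scale recovers the imposed 15.6× expansion to
0.002%, and the distortion curve of this undistorted pair stays below
0.15% of the measurement length — the noise floor of the metrology.
Imposing a 3% shear anisotropy (`shear = diag(c(1.03, 1/1.03))`) raises
the similarity-pipeline curve to ~1.9% mean relative error while an
affine pre-registration absorbs it back to ~0.03% — the signature used
to attribute distortion to anisotropic sample handling.

Expansion factor from nuclear areas:

```r
nuc  <- make_scene("nuclei", seed = 3)
pre  <- render(nuc, imaging_params(), seed = 1)
post <- deform_scene(nuc, deformation_spec(scale = 15.6),
                     imaging_params(pixel_size_nm = 1600), seed = 2)$post
expansion_factor(nuclear_areas(pre),
                 nuclear_areas(post, min_area_um2 = 20 * 15.6^2))
#> <expansion_estimate> 15.596 (nuclear_area, n = 6, sd 1.189)
```

Morphometry on a simulated Golgi stack (4 cisternae, 64 nm spacing,
imaged after 15× expansion):

```r
g  <- make_scene("golgi", params = list(field_size_nm = 4000, spacing_nm = 64,
                                        n_cisternae = 4, angle = 0,
                                        length_nm = 1500, linear_density = 400),
                 seed = 2)
dg <- deform_scene(g, deformation_spec(scale = 15),
                   imaging_params(pixel_size_nm = 120), seed = 1)
ctr <- 4000 * 15 / 2 / 120
prof <- thick_line_profile(dg$post, c(ctr, ctr - 25), c(ctr, ctr + 25),
                           thickness_px = 10)
peak_spacing(prof, expansion_factor = 15)
#> <morphometric_result:peak_spacing> n = 3, mean 64.0 +/- 0.3 nm, median 64.0 (IQR 0.3)
```

A pipeline driver (`run_pipeline()`) and a thin command-line wrapper
(`inst/cli/exm.R`) expose the same steps as `simulate`, `register`,
`distortion`, `expansion-factor`, `morphometry` and `signal` commands
writing TIFF/CSV/JSON artifacts stamped with the configuration hash and
seed.

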