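---
title: "Quantifying keratohyalin granule maturation in 3D: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying keratohyalin granule maturation in 3D: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(khgmorph)
```

## The measurement problem

Keratohyalin granules (KHGs) are dense, profilaggrin-containing condensates
in the granular layer of the epidermis. During keratinocyte
differentiation they change in number, size and shape — from small round
granules to elongated tubes, rings and, past a length of about 3 µm, fused
aggregates — and their spatial distribution shifts toward the nucleus and
the uppermost epidermal layers. `khgmorph` turns multi-channel 3D confocal
stacks into per-granule geometric descriptors and population-level
statistics that capture exactly these changes, together with the
preprocessing (PSF modelling, deconvolution) and the control analyses
(bead fields, colocalization, LAURDAN membrane order) that such a study
needs.

Everything in the package is exercised end-to-end on synthetic volumetric
phantoms with closed-form ground truth, so each claim the pipeline makes
about an image can be checked against an analytic value.

## Pipeline and models

### Phantoms with analytic truth

The generator renders five primitives — sphere, ellipsoid, capsule
(cylinder with hemispherical caps), torus and partial torus — chosen
because they cover the observed KHG morphologies (round, flattened,
tubular, ring, open half-ring) *and* have closed-form volume, surface
area and longest extent, which is what makes parameter-recovery testing
possible. The literature shows these shapes in images but never
parameterizes them, so the default size ranges are illustrative: single
granules are drawn with every half-extent above the axial resolution limit
(diameters roughly 0.9–1.7 µm, lengths below 2.9 µm) and aggregates as
capsules of length 3.3–4.7 µm, keeping the two classes unambiguous with
respect to the 3-µm rule.

Rendering is anti-aliased: each voxel stores the analytic inside-fraction
approximated by 2× supersampling per axis. This removes the systematic
volume bias of binary voxelization; the voxel-count volume of a noiseless
shape converges to within 2% of the closed form once the smallest feature
spans about 10 voxels.

Realism of the optics and noise follows the standard confocal model:
convolution with an anisotropic Gaussian PSF and Poisson shot noise at a
configurable photon scale plus optional Gaussian read noise. Arrays are
ordered `(z, y, x)` with `z = 1` the basal side, matching the convention
that normalized epidermal height is measured from the bottom of the
tissue. What the phantoms deliberately do *not* emulate: STED
photophysics, antibody-labelling chemistry, autofluorescent background
structure, depth-dependent scattering, or granule motion. Tests passing on
phantoms therefore validate the measurement chain, not the biology of any
particular specimen.

### PSF and deconvolution

The theoretical PSF is a separable anisotropic Gaussian with defaults
σ_lateral = 0.1 µm and σ_axial = 0.4 µm, reflecting the ~200 nm lateral /
~800 nm axial diffraction-limited confocal resolution (FWHM ≈ 2.355 σ).
An optional linear axial inflation, σ_axial·(1 + c·depth), models
depth-dependent blur; the coefficient defaults to 0 because no quantitative
form for the depth adjustment is established. Kernels are integrated over
voxel bins, normalized to unit mass, and refuse to truncate below 99.9% of
the Gaussian mass.

The empirical alternative estimates the PSF from a bead control field
(1-µm fluorescent beads in gel). Each isolated bead is fitted by
intensity-weighted second moments; finite bead size is removed by
quadrature subtraction, σ²_psf = σ²_meas − R²/5, exact because variances
add under convolution and a uniform ball of radius R has per-axis variance
R²/5 regardless of profile shape. Beads touching the border or closer than
two diameters to a neighbour ("merged") are excluded; at least three
usable beads are required.

Deconvolution is Richardson–Lucy, the open maximum-likelihood standard for
Poisson-noise imagery (commercial packages use the closely related CMLE;
bit-level equivalence with any proprietary implementation is not a goal,
restoration-quality properties are). The default of 40 iterations balances
resolution recovery against noise amplification and is configurable.
Convolutions are periodic-boundary FFTs, so with a normalized kernel total
intensity is conserved exactly and a spatially constant image is a fixed
point; negatives arising from FFT round-off are clamped to zero.

### Segmentation and meshing

Granules are the 26-connected components above a threshold (absolute,
fraction-of-maximum, or Otsu's criterion — the default, since no published
threshold exists for this assay). 26-connectivity avoids splitting thin
diagonal tubes. Objects whose bounding box is narrower than 0.2 µm
laterally or 0.8 µm axially are below the microscope's sampling limit and
discarded (counted in the log). Labels are deterministic, ordered by
centroid (z, y, x). Touching granules remain one object by design: the
assay treats contacting granules as aggregates, so no watershed splitting
is applied.

Isosurfaces use marching tetrahedra (each grid cell split into six
tetrahedra around a fixed diagonal). Unlike classic marching cubes this
has no ambiguous cases, so any level set not touching the border yields a
closed 2-manifold — every edge borders exactly two triangles — which the
volume computation requires. Before triangulation the cropped field is
smoothed with a small Gaussian (σ = 0.6 voxel by default): meshing a
near-binary field directly produces a jagged surface whose area
overestimates the true one by several percent, while smoothing trades this
for a slight curvature-driven shrinkage of thin features. At σ = 0.6 voxel
both biases stay within ~3% for features ≥ 6 voxels across; σ in 0.6–1
voxel is a reasonable range, and 0 disables smoothing.

The nucleus model keeps the largest connected component, fills interior
holes by flood-filling the background from the volume border, and meshes
the filled mask.

### Morphometry

Volume is the divergence-theorem sum of signed tetrahedra over the closed
mesh (orientation-corrected); area is the sum of triangle areas. Length is
the largest extent of the principal-axes-oriented bounding box of the
object's voxels, with each extent including the projection of one voxel
cuboid onto its axis (the box encloses voxels, not voxel centres); the two
remaining extents are reported as axial width (axis best aligned with z)
and lateral width. Sphericity is the Wadell form

$$\mathrm{Sph} = \pi^{1/3} (6V)^{2/3} / A,$$

the ratio of the surface area of the volume-equivalent sphere to the
object's area: dimensionless, exactly 1 for an ideal sphere, strictly
decreasing with elongation. A typographically common variant,
π^(1/3)(6V/A)^(2/3), carries units of length^(2/3) and cannot equal 1 for
a sphere of arbitrary radius; it is available behind
`sphericity(..., literal_form = TRUE)` for comparison only. The aspect
ratios are AxRatio = length / axial width and LaRatio = length / lateral
width — the two are sometimes conflated in print; here the names match the
widths they divide by. Size classification uses the principal-axes length
against the 3-µm cutoff: longer objects are aggregates.

### Spatial statistics

The signed granule–nucleus distance is the Euclidean distance from the
granule centroid to the nearest nucleus *surface* voxel (a mask voxel with
a 6-neighbour in background), computed by an exact distance transform that
honours anisotropic spacing, with a negative sign inside the mask.
Coordinate-wise sign rules are ambiguous for non-convex surfaces; the
surface-distance formulation reproduces the same inside/outside dichotomy
and is well defined for every nucleus shape. It agrees with a brute-force
nearest-surface-voxel search to within one voxel diagonal, and a centroid
on the surface scores zero to within half a voxel.

Heights are normalized as z / (local sample height) into [0, 1].
Group summaries report mean, SD and SDM per condition — SDM is read as the
standard error of the mean, sd/√n, the usual error-bar convention in
granule-population plots — optionally split at the 3-µm size classes.
Trends over a numeric condition (e.g. calcium concentration in mM) use
regression splines of degree 1–3 with 0–4 interior knots, the model chosen
by generalized cross-validation, GCV = n·RSS/(n − p)²; ties go to the
smaller model, so a noiseless polynomial of degree ≤ 3 is reproduced
exactly. Unpaired two-sample comparisons use Welch's t-test; the
degenerate all-constant case reports t = 0 rather than 0/0.

Colocalization is the Pearson correlation of two channels over a
configurable mask (whole volume by default, since the region of interest
used in published analyses is rarely stated). Zero variance makes the
coefficient undefined and is flagged as `NA` with a warning — never
silently reported as 0. Manders or Costes variants are out of scope.

### LAURDAN generalized polarization

GP = (I₄₄₀ − I₄₉₀)/(I₄₄₀ + I₄₉₀) per pixel, the only normalization
consistent with the documented [−1, 1] range; higher GP means more ordered
(stiffer) membranes. Pixels whose total intensity falls below a floor
(1% of the masked maximum total by default) are noise-dominated and marked
undefined rather than contributing arbitrary ratios. The GP distribution
is binned into 64 bins over [−1, 1] — the fit operates on the histogram,
matching how GP distributions are reported — and decomposed into two
Gaussians by Levenberg–Marquardt least squares on the bin counts,
initialised at the two best-separated smoothed modes (quartiles as
fallback). The lower-mean component is labelled cytosol, the higher-mean
membrane. A failed two-component fit falls back to a single Gaussian and
is flagged; an essentially constant GP map is reported as degenerate. The
mask is optional and logged, since whole-image versus cell-masked pooling
is a per-study choice.

## Numerical and I/O choices

* **Thresholds**: Otsu's criterion runs on a 256-level histogram of the
  channel range. Iso-levels for meshing default to the segmentation
  threshold.
* **Mesh smoothing**: σ = 0.6 voxel pre-smoothing, rationale above.
* **Distance transform**: Felzenszwalb–Huttenlocher exact squared-distance
  envelopes per axis with physical spacing; no chamfer approximation.
* **Degenerate inputs**: all-background images segment to an empty list
  (not an error); a threshold above the maximum warns; collinear voxel
  sets get a one-voxel width and a flag; objects one voxel thin refuse to
  mesh; an empty nucleus channel is an error.
* **TIFF I/O**: volumes are written as 32-bit fixed-point multi-page TIFF
  with a JSON sidecar carrying voxel spacing, channel names and a
  power-of-two intensity scale. Power-of-two scaling is exact in floating
  point, and values already on the file's dyadic grid — including every
  integer-valued photon-count image below 2³¹ — round-trip bit-for-bit.
  Reading a TIFF without metadata requires an explicit spacing; there is
  no silent default voxel size.
* **Determinism**: every stochastic generator takes a seed; a fixed seed
  yields bit-identical volumes and truth tables, and seeded generation
  restores the caller's RNG state.

## Problem sizes used in the shipped tests

The test suite validates the pipeline at desk scale: single-shape phantoms
of 40–120 voxels per axis; a 100-granule recovery population rendered in
four 16 × 16 × 8 µm volumes at 50-nm voxels (median absolute relative
errors: volume and area ≈ 1–2%, length ≈ 4%, size-class accuracy 100%);
a 1-µm bead control at 50-nm voxels deconvolved for 40 iterations
(recovered extent within 10%); GP phantoms of 10⁵ pixels (fitted means
within ±0.02); and twenty random nucleus phantoms for the distance-oracle
comparison. Headline population statistics from donor tissue (e.g.
aggregate percentages over ~10⁴ granules across donors) depend on images
that are not publicly deposited and are out of scope here; the package
validates the measurement machinery that produces such numbers.

## Known limitations

* Touching granules are measured as one object (intended for aggregates,
  but true incidental contacts are not split).
* The ellipsoid surface-area ground truth uses the Thomsen approximation
  (≤ ~1.1% error), which is folded into recovery tolerances.
* Richardson–Lucy with periodic boundaries assumes objects away from the
  volume border; bright structures at the border would wrap.
* The PSF model is Gaussian; real confocal PSFs have Airy sidelobes and
  depth-dependent aberrations the linear axial inflation only sketches.
* Sub-resolution granules (< 0.2 µm lateral / 0.8 µm axial) are filtered
  out by design and never reach the statistics.
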