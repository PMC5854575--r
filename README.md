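# khgmorph

3D morphometry, deconvolution and spatial statistics for keratohyalin
granule (KHG) imaging.

Keratohyalin granules are profilaggrin-storing protein condensates in
granular-layer keratinocytes. As the epidermis stratifies, KHGs grow,
elongate, form rings and fuse into aggregates, and their population shifts
toward the nucleus and the uppermost epidermal layers. `khgmorph`
implements the quantitative machinery needed to measure this from
multi-channel 3D confocal stacks, for cell biologists and image analysts
working on epidermal differentiation:

* **Synthetic phantoms** with exact analytic ground truth — spheres,
  ellipsoids, capsules (tubes), tori (rings) and half-rings, plus epidermal
  sheets with height gradients, 1-µm bead-in-gel control fields, and
  two-channel LAURDAN images with a known GP mixture. Every downstream
  stage is testable without any data download.
* **Imaging core** — TIFF volume I/O with voxel-size metadata, theoretical
  and bead-derived anisotropic Gaussian PSF models, and Richardson–Lucy
  deconvolution.
* **Segmentation** — isosurface thresholding (Otsu / absolute / relative),
  26-connected 3D labelling, resolution-limit filtering (0.2 µm lateral /
  0.8 µm axial by default), marching-tetrahedra surface meshes, nucleus
  model with hole filling.
* **Morphometry** — per-granule volume V and surface area A from the closed
  isosurface mesh, principal-axis length and widths, aspect ratios, the
  single/aggregate size dichotomy at 3 µm, and sphericity

  $$\mathrm{Sph} = \frac{\pi^{1/3}\,(6V)^{2/3}}{A},$$

  which is exactly 1 for an ideal sphere and below 1 for elongated or
  ring-shaped granules.
* **Spatial statistics** — signed Euclidean distance from granule centroids
  to the nucleus surface (negative inside), height normalization to the
  local epidermis thickness, per-condition means ± SDM with smoothing-spline
  trend curves (degree 1–3, chosen by generalized cross-validation), and
  Pearson colocalization.
* **LAURDAN GP** — per-pixel generalized polarization
  GP = (I₄₄₀ − I₄₉₀)/(I₄₄₀ + I₄₉₀) ∈ [−1, 1] as a membrane-order
  (stiffness) readout, and double-Gaussian decomposition of the GP
  histogram into cytosolic and membrane populations.

## Worked example

Render a 12-granule cell phantom around an ellipsoidal nucleus, blur it
with a confocal PSF, add shot noise, then run the full measurement
pipeline:

```r
library(khgmorph)

spacing <- c(0.05, 0.05, 0.05)                      # 50-nm voxels, um
psf <- theoretical_psf(sigma_lateral = 0.08, sigma_axial = 0.2, spacing)

specs <- sample_granule_specs(12, region_um = c(10, 10, 5),
                              aggregate_fraction = 0.15, seed = 2026)
nucleus <- shape_spec("ellipsoid", center = c(5, 5, 2.5),
                      size = list(a = 2.0, b = 1.5, c = 1.2))
ph <- compose_cell_phantom(specs, nucleus, voxel_spacing = spacing,
                           grid_shape = c(101, 201, 201), psf = psf,
                           noise = noise_model(photon_scale = 200, seed = 2026))

dec  <- richardson_lucy_deconvolve(ph$grid, psf, iterations = 40)
objs <- segment_granules(dec, channel = "granules", threshold = "otsu")
rec  <- granule_morphometry(dec, objs)
nuc  <- segment_nucleus(dec, channel = "nucleus")
rec$nucleus_distance_um <- signed_distance_to_nucleus(
  cbind(rec$centroid_x_um, rec$centroid_y_um, rec$centroid_z_um), nuc)

rec[, c("volume_um3", "area_um2", "length_um", "sphericity",
        "size_class", "nucleus_distance_um")]
```

```
# A tibble: 12 × 6
   volume_um3 area_um2 length_um sphericity size_class nucleus_distance_um
        <dbl>    <dbl>     <dbl>      <dbl> <chr>                    <dbl>
 1      0.402     2.66     0.995      0.990 single                    2.02
 2      0.603     3.57     1.44       0.966 single                    3.76
 3      0.594     3.50     1.31       0.978 single                    2.79
 4      0.826     4.47     1.69       0.953 single                    2.79
 5      0.342     2.39     0.952      0.990 single                    1.22
 6      2.80     12.6      2.38       0.760 single                    1.35
 7      2.05     10.0      3.60       0.778 aggregate                 2.90
 8      0.392     2.62     0.976      0.989 single                    3.03
 9      0.860     4.53     1.62       0.964 single                    2.71
10      0.502     3.09     1.05       0.990 single                    1.06
11      0.807     4.23     1.22       0.991 single                    2.04
12      0.663     3.71     1.15       0.991 single                    4.12
```

All 12 rendered granules are recovered. Round granules score sphericity
≈ 0.99; row 6 is a ring (torus), whose low sphericity (0.76) flags the
non-spherical morphology; row 7 is a 3.6-µm elongated aggregate, classified
by the 3-µm length rule. Distances are µm from the nucleus surface
(negative values would mean inside the nucleus).

Population-level summaries follow the same granule table, e.g.
`trend_and_group_stats(tab, "volume_um3", "calcium_mM", size_split = TRUE)`
for per-condition means ± SDM with spline trends, and
`fit_gp_populations(gp_image(grid))` for LAURDAN membrane/cytosol
decomposition.

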