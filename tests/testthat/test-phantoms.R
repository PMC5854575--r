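test_that("closed-form geometry matches analytic values", {
  sp <- shape_spec("sphere", c(2, 2, 2), list(radius = 0.5))
  expect_equal(shape_volume(sp), 4 * pi / 3 * 0.5^3, tolerance = 1e-12)
  to <- shape_spec("torus", c(3, 3, 3), list(major = 1, minor = 0.25))
  expect_equal(shape_volume(to), 2 * pi^2 * 1 * 0.25^2, tolerance = 1e-12)
  expect_equal(shape_area(to), 4 * pi^2 * 1 * 0.25, tolerance = 1e-12)
  ca <- shape_spec("capsule", c(5, 5, 5), list(half_length = 2, radius = 0.5))
  expect_equal(shape_extent(ca), 5)
  expect_error(shape_spec("sphere", c(0, 0, 0), list(radius = -1)), "> 0")
  expect_error(shape_spec("half_torus", c(0, 0, 0), list(major = 1, minor = 0.2),
                          sweep_deg = 400), "sweep")
})

test_that("voxel-count volume of rendered shapes converges to the analytic value", {
  # smallest feature >= 10 voxels in every case
  s <- 0.04
  shapes <- list(
    shape_spec("sphere", c(2, 2, 2), list(radius = 0.5)),
    shape_spec("ellipsoid", c(2, 2, 2), list(a = 0.9, b = 0.5, c = 0.4),
               orientation = c(1, 1, 0)),
    shape_spec("capsule", c(2, 2, 2), list(half_length = 0.8, radius = 0.3),
               orientation = c(1, 0, 1)),
    shape_spec("torus", c(2, 2, 2), list(major = 0.8, minor = 0.25)),
    shape_spec("half_torus", c(2, 2, 2), list(major = 0.8, minor = 0.25),
               sweep_deg = 180)
  )
  for (spec in shapes) {
    ph <- render_shape(spec, iso_spacing(s), c(101, 101, 101))
    vox_vol <- sum(get_channel(ph$grid)) * s^3
    expect_lt(abs(vox_vol / shape_volume(spec) - 1), 0.02, label = spec$kind)
    expect_equal(ph$truth$volume_um3, shape_volume(spec))
  }
})

test_that("shapes exceeding the grid raise an error naming the extent", {
  sp <- shape_spec("sphere", c(0.3, 2, 2), list(radius = 0.5))
  expect_error(render_shape(sp, iso_spacing(0.1), c(41, 41, 41)),
               "exceeds grid bounds.*x axis")
})

test_that("cell phantom: object count, empty case, determinism", {
  centers <- as.matrix(expand.grid(x = c(2, 5, 8), y = c(2, 5, 8), z = 2))
  specs <- lapply(seq_len(nrow(centers)), function(i)
    shape_spec("sphere", centers[i, ], list(radius = 0.6)))
  specs <- c(specs, list(shape_spec("sphere", c(5, 5, 4), list(radius = 0.6))))
  ph <- compose_cell_phantom(specs, NULL, voxel_spacing = iso_spacing(0.1),
                             grid_shape = c(61, 101, 101))
  objs <- segment_granules(ph$grid, threshold = 0.5, channel = "granules")
  expect_length(objs, 10L)

  empty <- compose_cell_phantom(list(), NULL, voxel_spacing = iso_spacing(0.1),
                                grid_shape = c(11, 11, 11))
  expect_equal(nrow(empty$truth), 0L)
  expect_true(all(get_channel(empty$grid, "granules") == 0))

  nm <- noise_model(photon_scale = 50, seed = 11)
  one <- list(shape_spec("sphere", c(1, 1, 1), list(radius = 0.4)))
  a <- compose_cell_phantom(one, NULL, voxel_spacing = iso_spacing(0.1),
                            grid_shape = c(21, 21, 21), noise = nm)
  b <- compose_cell_phantom(one, NULL, voxel_spacing = iso_spacing(0.1),
                            grid_shape = c(21, 21, 21), noise = nm)
  expect_identical(a$grid$data, b$grid$data)
  expect_identical(a$truth, b$truth)
})

test_that("cell phantom records analytic signed nucleus distances", {
  nuc <- shape_spec("sphere", c(5, 5, 5), list(radius = 2))
  specs <- list(
    shape_spec("sphere", c(5, 5, 5.5), list(radius = 0.3)),  # inside
    shape_spec("sphere", c(8.5, 5, 5), list(radius = 0.3))   # outside, 1.5 from surface
  )
  ph <- compose_cell_phantom(specs, nuc, voxel_spacing = iso_spacing(0.1),
                             grid_shape = c(101, 101, 101))
  expect_equal(ph$truth$nucleus_distance_um, c(-1.5, 1.5), tolerance = 1e-9)
})

test_that("epidermis phantom: height gradient, bounds and aggregate fraction", {
  expect_error(compose_epidermis_phantom(layer_count = 1), "layer_count")

  ep <- compose_epidermis_phantom(layer_count = 8, n_granules = 1000,
                                  aggregate_fraction = 0.05,
                                  render = FALSE, seed = 5)
  h <- ep$truth$normalized_height
  expect_true(all(h >= 0 & h <= 1))
  counts <- tabulate(ep$truth$height_bin, nbins = 8)
  expect_gt(cor(seq_len(8), counts, method = "spearman"), 0)
  frac <- mean(ep$truth$extent_um > 3)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 1000)
  expect_gt(frac, ci[1])
  expect_lt(frac, ci[2])
  expect_true(all(ep$truth$size_class[ep$truth$extent_um > 3] == "aggregate"))
})

test_that("bead phantom extents and merged flags behave", {
  ph <- make_bead_phantom(1, iso_spacing(0.05), n_beads = 3)
  obj <- segment_granules(ph$grid, threshold = 0.5, channel = 1)
  expect_length(obj, 3L)
  ext <- principal_extents(obj[[1]], ph$grid$spacing)
  expect_lt(abs(ext[["length_um"]] - 1), 0.05 + 1e-9)  # within one voxel
  expect_false(any(ph$truth$merged))

  expect_error(make_bead_phantom(0.08, iso_spacing(0.05)), "twice the lateral")

  psf <- theoretical_psf(0.08, 0.25, iso_spacing(0.05))
  close_pos <- rbind(c(2, 2, 2), c(2.1, 2, 2), c(5, 2, 2))
  phm <- make_bead_phantom(1, iso_spacing(0.05), psf = psf, positions = close_pos)
  expect_equal(phm$truth$merged, c(TRUE, TRUE, FALSE))

  # blur pushes the axial full-width-half-maximum beyond the true 1 um
  ph1 <- make_bead_phantom(1, iso_spacing(0.05), psf = psf, n_beads = 1)
  v <- get_channel(ph1$grid)
  pk <- which(v == max(v), arr.ind = TRUE)[1, ]
  prof <- v[, pk[2], pk[3]]
  half <- max(prof) / 2
  above <- which(prof >= half)
  lo <- min(above); hi <- max(above)
  xlo <- lo - 1 + (half - prof[lo - 1]) / (prof[lo] - prof[lo - 1])
  xhi <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
  fwhm <- (xhi - xlo) * 0.05
  expect_gt(fwhm, 1)
})

test_that("GP phantom encodes the drawn mixture exactly", {
  rm2 <- matrix(1L, 50, 50)
  ph0 <- make_gp_phantom(rm2, gp_means = 0, gp_sds = 0, seed = 1)
  expect_true(all(get_channel(ph0$grid, "I440") == get_channel(ph0$grid, "I490")))

  ph1 <- make_gp_phantom(rm2, gp_means = 1, gp_sds = 0, seed = 1)
  expect_true(all(get_channel(ph1$grid, "I490") == 0))

  expect_error(make_gp_phantom(rm2, gp_means = 1.2, gp_sds = 0), "\\[-1, 1\\]")

  rm <- matrix(rep(1:2, each = 110 * 110), 110, 220)
  ph <- make_gp_phantom(rm, gp_means = c(0, 0.5), gp_sds = c(0.1, 0.1), seed = 3)
  gp <- gp_image(ph$grid)
  for (r in 1:2) {
    vals <- gp[array(rm, dim(gp)) == r]
    expect_lt(abs(mean(vals) - c(0, 0.5)[r]), 0.02)
  }
  # before noise, recomputed GP equals the drawn values exactly
  defined <- !is.na(ph$gp_true)
  expect_equal(gp[defined], ph$gp_true[defined], tolerance = 1e-12)
})

test_that("every rendered object has exactly one truth row", {
  specs <- sample_granule_specs(8, c(8, 8, 4), seed = 42)
  ph <- compose_cell_phantom(specs, NULL, voxel_spacing = iso_spacing(0.06),
                             grid_shape = c(68, 135, 135))
  objs <- segment_granules(ph$grid, threshold = 0.5, channel = "granules")
  expect_length(objs, nrow(ph$truth))
})
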