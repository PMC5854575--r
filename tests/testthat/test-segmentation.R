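test_that("component count, resolution filter and centroids", {
  specs <- list(shape_spec("sphere", c(2, 2, 2), list(radius = 0.6)),
                shape_spec("sphere", c(5, 5, 2), list(radius = 0.6)))
  ph <- compose_cell_phantom(specs, NULL, voxel_spacing = iso_spacing(0.1),
                             grid_shape = c(41, 71, 71))
  objs <- segment_granules(ph$grid, threshold = 0.5, channel = "granules")
  expect_length(objs, 2L)
  # intensity-weighted centroid of a symmetric sphere: within half a voxel
  expect_lt(max(abs(objs[[1]]$centroid - c(2, 2, 2))), 0.05)

  # a 0.1-um speck is below the sampling limit and filtered under defaults
  speck <- compose_cell_phantom(
    list(shape_spec("sphere", c(1, 1, 1), list(radius = 0.05)),
         shape_spec("sphere", c(3, 3, 1), list(radius = 0.6))),
    NULL, voxel_spacing = iso_spacing(0.05), grid_shape = c(41, 101, 101))
  o2 <- segment_granules(speck$grid, threshold = 0.1, channel = "granules")
  expect_length(o2, 1L)
  expect_equal(attr(o2, "log")$n_filtered, 1L)

  # all-background image: empty list, not an error
  blank <- voxel_grid(array(0, c(8, 8, 8)), iso_spacing(0.1))
  expect_length(segment_granules(blank, threshold = 0.5), 0L)
  # threshold above the maximum: empty with warning
  lit <- voxel_grid(array(1, c(8, 8, 8)), iso_spacing(0.1))
  expect_warning(out <- segment_granules(lit, threshold = 5), "maximum")
  expect_length(out, 0L)
})

test_that("labelling is deterministic and filtering only removes voxels", {
  specs <- sample_granule_specs(6, c(7, 7, 4), seed = 9)
  ph <- compose_cell_phantom(specs, NULL, voxel_spacing = iso_spacing(0.08),
                             grid_shape = c(51, 89, 89))
  a <- segment_granules(ph$grid, threshold = 0.5, channel = "granules")
  b <- segment_granules(ph$grid, threshold = 0.5, channel = "granules")
  expect_identical(lapply(a, `[[`, "voxels"), lapply(b, `[[`, "voxels"))
  # label ids ordered by centroid z, y, x
  cz <- vapply(a, function(o) o$centroid[3], numeric(1))
  expect_true(all(diff(cz) >= -1e-9))
  n_above <- sum(get_channel(ph$grid, "granules") > 0.5)
  expect_lte(sum(vapply(a, `[[`, integer(1), "n_voxels")), n_above)
  # perfect detection on well-separated noiseless objects
  expect_length(a, length(specs))
})

test_that("isosurface meshes have the right topology and units", {
  sph <- sphere_phantom(radius = 0.8, s = 0.05)
  objs <- segment_granules(sph$phantom$grid, threshold = 0.5)
  mesh <- extract_isosurface_mesh(objs[[1]], sph$phantom$grid, iso_level = 0.5)
  expect_true(mesh$closed)
  expect_equal(euler_characteristic(mesh), 2)

  tor <- render_shape(shape_spec("torus", c(2, 2, 2), list(major = 0.8, minor = 0.3)),
                      iso_spacing(0.05), c(81, 81, 81))
  to <- segment_granules(tor$grid, threshold = 0.5, min_extent_axial = 0.2)
  tm <- extract_isosurface_mesh(to[[1]], tor$grid, iso_level = 0.5)
  expect_true(tm$closed)
  expect_equal(euler_characteristic(tm), 0)

  # vertex coordinates scale linearly with voxel spacing
  arr <- get_channel(sph$phantom$grid)
  o1 <- segment_granules(arr, threshold = 0.5, spacing = iso_spacing(0.05))
  m1 <- extract_isosurface_mesh(o1[[1]], arr, iso_level = 0.5, spacing = iso_spacing(0.05))
  m2 <- extract_isosurface_mesh(o1[[1]], arr, iso_level = 0.5, spacing = iso_spacing(0.1))
  expect_equal(m2$vertices, m1$vertices * 2, tolerance = 1e-9)

  # single-voxel-thin objects cannot be meshed
  thin <- array(0, c(9, 9, 9)); thin[5, 3:7, 3:7] <- 1
  ot <- segment_granules(thin, threshold = 0.5, spacing = iso_spacing(0.3),
                         min_extent_lateral = 0, min_extent_axial = 0)
  expect_error(extract_isosurface_mesh(ot[[1]], thin, iso_level = 0.5,
                                       spacing = iso_spacing(0.3)),
               "degenerate")
})

test_that("nucleus segmentation recovers volume, fills holes, keeps largest blob", {
  nuc <- shape_spec("ellipsoid", c(4, 4, 3), list(a = 2.2, b = 1.6, c = 1.2),
                    orientation = c(1, 0.3, 0))
  ph <- compose_cell_phantom(list(), nuc, voxel_spacing = iso_spacing(0.08),
                             grid_shape = c(76, 101, 101))
  nm <- segment_nucleus(ph$grid, threshold = 0.5)
  vol <- sum(nm$mask) * 0.08^3
  expect_lt(abs(vol / shape_volume(nuc) - 1), 0.05)
  expect_true(nm$mesh$closed)
  lab <- khgmorph:::cc_label_3d(as.vector(nm$mask), dim(nm$mask), 26L)
  expect_equal(attr(lab, "n_components"), 1L)

  # two blobs: the larger is kept, the event reported
  two <- array(0, c(30, 30, 30))
  two[5:20, 5:20, 5:20] <- 1     # large
  two[25:27, 25:27, 25:27] <- 1  # small
  expect_message(nm2 <- segment_nucleus(two, threshold = 0.5,
                                        spacing = iso_spacing(0.1)),
                 "discarded")
  expect_false(nm2$mask[26, 26, 26])
  expect_true(nm2$mask[10, 10, 10])

  # interior holes are filled
  hole <- array(0, c(24, 24, 24))
  hole[6:18, 6:18, 6:18] <- 1
  hole[11:13, 11:13, 11:13] <- 0
  nm3 <- segment_nucleus(hole, threshold = 0.5, spacing = iso_spacing(0.1))
  expect_true(all(nm3$mask[11:13, 11:13, 11:13]))

  empty <- voxel_grid(array(0, c(8, 8, 8)), iso_spacing(0.1))
  expect_error(segment_nucleus(empty), "no nucleus")
})
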