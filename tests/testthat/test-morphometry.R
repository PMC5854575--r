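cube_mesh <- function(side = 1) {
  v <- as.matrix(expand.grid(x = c(0, side), y = c(0, side), z = c(0, side)))
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  khgmorph:::new_iso_mesh(v, f)
}

test_that("mesh geometry: closed forms, exact polyhedra, homogeneity", {
  sph <- sphere_phantom(radius = 1, s = 0.05)
  objs <- segment_granules(sph$phantom$grid, threshold = 0.5)
  mesh <- extract_isosurface_mesh(objs[[1]], sph$phantom$grid, iso_level = 0.5)
  g <- mesh_geometry(mesh)
  expect_lt(abs(g[["volume_um3"]] / (4 * pi / 3) - 1), 0.02)
  expect_lt(abs(g[["area_um2"]] / (4 * pi) - 1), 0.02)

  cm <- cube_mesh(1)
  expect_true(cm$closed)
  gc <- mesh_geometry(cm)
  expect_equal(gc[["volume_um3"]], 1)
  expect_equal(gc[["area_um2"]], 6)

  s <- 3.7
  scaled <- khgmorph:::new_iso_mesh(mesh$vertices * s, mesh$faces)
  gs <- mesh_geometry(scaled)
  expect_equal(gs[["volume_um3"]], g[["volume_um3"]] * s^3, tolerance = 1e-9)
  expect_equal(gs[["area_um2"]], g[["area_um2"]] * s^2, tolerance = 1e-9)

  open_mesh <- khgmorph:::new_iso_mesh(cm$vertices, cm$faces[-1, ])
  expect_false(open_mesh$closed)
  expect_error(mesh_geometry(open_mesh), "not closed")
  expect_gt(mesh_area(open_mesh), 0)
})

test_that("principal extents recover box and sphere dimensions", {
  s <- 0.05
  mk_box <- function(orientation) {
    spec <- shape_spec("ellipsoid", c(3, 3, 3), list(a = 1.5, b = 0.5, c = 0.25),
                       orientation = orientation)
    ph <- render_shape(spec, iso_spacing(s), c(121, 121, 121))
    segment_granules(ph$grid, threshold = 0.5, min_extent_axial = 0.2)[[1]]
  }
  # axis-aligned 3 x 1 x 0.5 um ellipsoid
  ob <- mk_box(c(1, 0, 0))
  ext <- principal_extents(ob, iso_spacing(s))
  expect_lt(abs(ext[["length_um"]] - 3), 2 * s)
  # rotated 45 degrees in-plane: same physical length within a voxel diagonal
  ob45 <- mk_box(c(1, 1, 0))
  ext45 <- principal_extents(ob45, iso_spacing(s))
  expect_lt(abs(ext45[["length_um"]] - 3), sqrt(3) * s + 1e-9)

  sph <- sphere_phantom(radius = 0.5, s = s)
  os <- segment_granules(sph$phantom$grid, threshold = 0.5, min_extent_axial = 0.2)[[1]]
  es <- principal_extents(os, iso_spacing(s))
  expect_true(all(abs(es - 1) < s + 1e-9))
  expect_true(es[["length_um"]] >= es[["width_lateral_um"]] - 1e-9)
})

test_that("sphericity formula and its structure", {
  expect_equal(sphericity(4 * pi / 3, 4 * pi), 1, tolerance = 1e-12)
  expect_equal(sphericity(1, 6), (pi / 6)^(1 / 3), tolerance = 1e-12)
  # fixed V, doubling A halves Sph
  expect_equal(sphericity(2, 10), 2 * sphericity(2, 20), tolerance = 1e-12)
  expect_error(sphericity(0, 5), "positive")
  expect_error(sphericity(5, -1), "positive")
  # literal typeset variant carries units and is only exposed for comparison
  expect_equal(sphericity(4 * pi / 3, 4 * pi, literal_form = TRUE),
               pi^(1 / 3) * (2)^(2 / 3), tolerance = 1e-12)
})

test_that("granule records classify sizes at the 3-um rule and are complete", {
  s <- 0.06
  big <- shape_spec("capsule", c(3, 3, 2), list(half_length = 1.3, radius = 0.45),
                    orientation = c(1, 0, 0))   # length 3.5
  small <- shape_spec("capsule", c(3, 8, 2), list(half_length = 0.55, radius = 0.45),
                      orientation = c(1, 0, 0)) # length 2.0
  ph <- compose_cell_phantom(list(big, small), NULL, voxel_spacing = iso_spacing(s),
                             grid_shape = c(68, 185, 101))
  objs <- segment_granules(ph$grid, threshold = 0.5, channel = "granules")
  rec <- granule_morphometry(ph$grid, objs)
  m <- order(rec$centroid_y_um)
  expect_equal(rec$size_class[m], c("aggregate", "single"))
  num <- vapply(rec[, c("volume_um3", "area_um2", "length_um", "width_lateral_um",
                        "width_axial_um", "sphericity", "ax_ratio", "la_ratio")],
                function(col) all(is.finite(col) & col > 0), logical(1))
  expect_true(all(num))
  expect_true(all(rec$length_um >= rec$width_lateral_um - 1e-9))
  expect_true(all(rec$length_um >= rec$width_axial_um - 1e-9))
  expect_true(all(rec$sphericity > 0 & rec$sphericity <= 1.05))
})

test_that("sphericity decreases with elongation; volume oracles agree", {
  s <- 0.05
  sph_rec <- function(spec, dims = c(101, 101, 101)) {
    ph <- render_shape(spec, iso_spacing(s), dims)
    ob <- segment_granules(ph$grid, threshold = 0.5, min_extent_axial = 0.2)
    list(rec = granule_morphometry(ph$grid, ob), grid = ph$grid, ob = ob[[1]])
  }
  round_ <- sph_rec(shape_spec("sphere", c(2.5, 2.5, 2.5), list(radius = 0.62)))
  prolate <- sph_rec(shape_spec("ellipsoid", c(2.5, 2.5, 2.5),
                                list(a = 1.81, b = 0.362, c = 0.362),
                                orientation = c(1, 0, 0)))
  # equal volumes by construction (5:1 prolate), sphericity strictly lower
  expect_lt(abs(prolate$rec$volume_um3 / round_$rec$volume_um3 - 1), 0.1)
  expect_lt(prolate$rec$sphericity, round_$rec$sphericity)
  expect_gt(round_$rec$sphericity, 0.95)

  # elongating a capsule at fixed radius: Len and AxRatio up, Sph down
  caps <- lapply(c(0.4, 0.8, 1.2), function(hl)
    sph_rec(shape_spec("capsule", c(3, 3, 3), list(half_length = hl, radius = 0.4),
                       orientation = c(0, 0, 1)), dims = c(121, 121, 121))$rec)
  lens <- vapply(caps, `[[`, numeric(1), "length_um")
  axr <- vapply(caps, `[[`, numeric(1), "ax_ratio")
  sphs <- vapply(caps, `[[`, numeric(1), "sphericity")
  expect_true(all(diff(lens) > 0))
  expect_true(all(diff(axr) > 0))
  expect_true(all(diff(sphs) < 0))

  # two independent volume oracles: mesh vs voxel count
  vox_vol <- round_$ob$n_voxels * s^3
  expect_lt(abs(round_$rec$volume_um3 / vox_vol - 1), 0.05)
})
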