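test_that("volume IO round-trips data, spacing and channels", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "vol.tif")
  # float32-representable intensities round-trip bit-for-bit
  set.seed(1)
  x <- array(sample(0:4095, 32 * 64 * 64, replace = TRUE) / 16, c(32, 64, 64))
  g <- voxel_grid(x, spacing = c(0.05, 0.05, 0.2))
  write_volume(g, f)
  r <- read_volume(f)
  expect_identical(r$data[[1]], x)
  expect_equal(unname(r$spacing), c(0.05, 0.05, 0.2), tolerance = 1e-6)

  # two channels of equal shape with names
  g2 <- voxel_grid(list(granules = x, nucleus = x / 2), spacing = c(0.1, 0.1, 0.3))
  f2 <- file.path(dir, "vol2.tif")
  write_volume(g2, f2)
  r2 <- read_volume(f2)
  expect_named(r2$data, c("granules", "nucleus"))
  expect_identical(dim(r2$data$granules), dim(r2$data$nucleus))
  expect_identical(r2$data$nucleus, x / 2)

  # no sidecar: spacing override required, missing spacing is an error
  f3 <- file.path(dir, "bare.tif")
  tiff::writeTIFF(lapply(1:4, function(i) matrix(runif(64), 8, 8)), f3,
                  bits.per.sample = 32L)
  expect_error(read_volume(f3), "spacing")
  r3 <- read_volume(f3, spacing = c(0.2, 0.2, 0.5))
  expect_equal(unname(r3$spacing), c(0.2, 0.2, 0.5))
})

test_that("theoretical PSF is normalized, anisotropic and depth-adjustable", {
  psf <- theoretical_psf(0.1, 0.4, iso_spacing(0.05))
  expect_equal(sum(psf$kernel), 1, tolerance = 1e-6)
  expect_true(all(psf$kernel >= 0))
  expect_equal(psf$sigma_axial / psf$sigma_lateral, 4)  # ~200/800 nm anisotropy

  base <- theoretical_psf(0.1, 0.4, iso_spacing(0.05), depth = 0, depth_coeff = 0.1)
  expect_identical(base$kernel, psf$kernel)
  deep <- theoretical_psf(0.1, 0.4, iso_spacing(0.05), depth = 10, depth_coeff = 0.1)
  expect_equal(deep$sigma_axial, 0.4 * 2)

  expect_error(theoretical_psf(0.1, 0.4, iso_spacing(0.05), n_sigma = 1),
               "99.9%")
  expect_error(psf_model(array(1, c(3, 3, 3)), iso_spacing(0.05), "gaussian",
                         sigma_lateral = 0.4, sigma_axial = 0.1),
               "anisotropy")
})

test_that("Richardson-Lucy: fixed point, flux conservation, non-negativity", {
  psf <- theoretical_psf(0.1, 0.2, iso_spacing(0.1))
  flat <- array(5, c(24, 24, 24))
  out <- richardson_lucy_deconvolve(flat, psf, iterations = 10)
  expect_lt(max(abs(out - flat)), 1e-6)

  psf2 <- theoretical_psf(0.08, 0.15, iso_spacing(0.05))
  ph <- sphere_phantom(radius = 0.8, s = 0.05)
  blurred <- convolve_fft(get_channel(ph$phantom$grid),
                          psf_kernel_at(psf2, iso_spacing(0.05)))
  dec <- richardson_lucy_deconvolve(blurred, psf2, iterations = 15)
  expect_true(all(dec >= 0))
  expect_lt(abs(sum(dec) / sum(blurred) - 1), 0.005)
  expect_identical(attr(dec, "rl_iterations"), 15L)

  bad <- psf2
  bad$kernel <- bad$kernel * 2
  expect_error(richardson_lucy_deconvolve(blurred, bad, 5), "normalized")
})

test_that("deconvolution restores the blurred bead extent and halves the MSE", {
  s <- 0.05
  psf <- theoretical_psf(0.08, 0.25, iso_spacing(s))
  blurred <- make_bead_phantom(1, iso_spacing(s), psf = psf, n_beads = 1)
  truth <- make_bead_phantom(1, iso_spacing(s), n_beads = 1,
                             positions = matrix(as.numeric(blurred$truth[1, c("center_x", "center_y", "center_z")]),
                                                ncol = 3),
                             grid_shape = unname(dim(blurred$grid)))
  ext_of <- function(grid) {
    ob <- segment_granules(grid, threshold = "otsu", channel = 1)
    principal_extents(ob[[1]], grid$spacing)[["length_um"]]
  }
  err_blurred <- abs(ext_of(blurred$grid) - 1)
  dec <- richardson_lucy_deconvolve(blurred$grid, psf, iterations = 40)
  err_dec <- abs(ext_of(dec) - 1)
  expect_lt(err_dec, err_blurred)

  ref <- get_channel(truth$grid)
  mse_blur <- mean((get_channel(blurred$grid) - ref)^2)
  mse_dec <- mean((get_channel(dec) - ref)^2)
  expect_lt(mse_dec, 0.5 * mse_blur)
})

test_that("PSF estimation from beads recovers the blur kernel", {
  s <- 0.05
  psf <- theoretical_psf(0.08, 0.25, iso_spacing(s))
  ph <- make_bead_phantom(1, iso_spacing(s), psf = psf, n_beads = 4)
  est <- estimate_psf_from_beads(ph$grid, known_diameter = 1)
  expect_lt(abs(est$sigma_lateral / 0.08 - 1), 0.10)
  expect_lt(abs(est$sigma_axial / 0.25 - 1), 0.10)
  expect_gte(attr(est, "n_beads"), 3)

  # invariance to global intensity scaling
  scaled <- ph$grid
  scaled$data[[1]] <- scaled$data[[1]] * 37.5
  est2 <- estimate_psf_from_beads(scaled, known_diameter = 1)
  expect_equal(est2$sigma_lateral, est$sigma_lateral, tolerance = 1e-9)

  # sub-voxel "point" beads: quadrature correction vanishes
  php <- make_bead_phantom(0.12, iso_spacing(s), psf = psf, n_beads = 4)
  estp <- estimate_psf_from_beads(php$grid, known_diameter = 0.12)
  expect_lt(abs(estp$sigma_lateral / 0.08 - 1), 0.15)

  empty <- voxel_grid(array(0, c(16, 16, 16)), iso_spacing(s))
  expect_error(estimate_psf_from_beads(empty, 1), "empty")
  two <- make_bead_phantom(1, iso_spacing(s), psf = psf, n_beads = 2)
  expect_error(estimate_psf_from_beads(two$grid, 1), ">= 3")
})
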