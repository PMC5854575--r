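#' Point-spread-function model
#'
#' Either a parametric anisotropic Gaussian (`form = "gaussian"`) or an
#' empirical kernel volume (`form = "empirical"`). Kernels are non-negative
#' and sum to 1; for Gaussian models the axial sigma must be at least the
#' lateral sigma (confocal anisotropy).
#'
#' @param kernel 3D `(z, y, x)` kernel array (odd dimensions).
#' @param spacing `c(dx, dy, dz)` um of the kernel grid.
#' @param form `"gaussian"` or `"empirical"`.
#' @param sigma_lateral,sigma_axial Gaussian sigmas in um (gaussian form).
#' @param depth_coeff Linear axial-sigma inflation per um of imaging depth.
#' @return A `psf_model` object.
#' @export
psf_model <- function(kernel, spacing, form = c("empirical", "gaussian"),
                      sigma_lateral = NA_real_, sigma_axial = NA_real_,
                      depth_coeff = 0) {
  form <- match.arg(form)
  if (any(kernel < 0)) stop("PSF kernel must be non-negative")
  s <- sum(kernel)
  if (s <= 0) stop("PSF kernel must have positive mass")
  if (abs(s - 1) > 1e-6) kernel <- kernel / s
  if (form == "gaussian") {
    stopifnot(is.finite(sigma_lateral), is.finite(sigma_axial),
              sigma_lateral > 0, sigma_axial > 0)
    if (sigma_axial < sigma_lateral)
      stop("confocal anisotropy requires sigma_axial >= sigma_lateral")
  }
  structure(list(kernel = kernel, spacing = as.numeric(spacing), form = form,
                 sigma_lateral = sigma_lateral, sigma_axial = sigma_axial,
                 depth_coeff = depth_coeff),
            class = "psf_model")
}

# one-axis Gaussian kernel integrated over voxel bins; checks captured mass
gauss_axis_kernel <- function(sigma, s, n_sigma) {
  R <- max(1L, ceiling(n_sigma * sigma / s))
  i <- (-R):R
  w <- pnorm((i + 0.5) * s, sd = sigma) - pnorm((i - 0.5) * s, sd = sigma)
  mass <- pnorm((R + 0.5) * s, sd = sigma) - pnorm(-(R + 0.5) * s, sd = sigma)
  list(w = w, mass = mass)
}

#' Theoretical confocal point-spread function
#'
#' A separable anisotropic Gaussian discretised on the voxel grid. The
#' defaults (sigma 0.1 um lateral, 0.4 um axial) reflect the ~200 nm lateral
#' and ~800 nm axial diffraction-limited resolution of a scanning confocal
#' microscope (FWHM ~ 2.355 sigma). Axial blur optionally grows linearly
#' with imaging depth: `sigma_axial_eff = sigma_axial * (1 + depth_coeff *
#' depth)`, with `depth_coeff = 0` by default.
#'
#' @param sigma_lateral,sigma_axial Gaussian sigmas in um.
#' @param voxel_spacing `c(dx, dy, dz)` um.
#' @param depth Imaging depth in um (used with `depth_coeff`).
#' @param depth_coeff Axial-sigma inflation per um of depth (default 0).
#' @param n_sigma Kernel half-support in sigmas (default 4); an error is
#'   raised if the truncated kernel captures less than 99.9% of the Gaussian
#'   mass.
#' @return A Gaussian [psf_model()].
#' @export
theoretical_psf <- function(sigma_lateral = 0.1, sigma_axial = 0.4,
                            voxel_spacing = c(0.05, 0.05, 0.05),
                            depth = 0, depth_coeff = 0, n_sigma = 4) {
  stopifnot(sigma_lateral > 0, sigma_axial > 0, depth >= 0)
  sig_ax <- sigma_axial * (1 + depth_coeff * depth)
  kx <- gauss_axis_kernel(sigma_lateral, voxel_spacing[1], n_sigma)
  ky <- gauss_axis_kernel(sigma_lateral, voxel_spacing[2], n_sigma)
  kz <- gauss_axis_kernel(sig_ax, voxel_spacing[3], n_sigma)
  if (kx$mass * ky$mass * kz$mass < 0.999)
    stop("kernel support captures < 99.9% of the Gaussian mass; increase n_sigma")
  k <- outer(outer(kz$w, ky$w), kx$w)      # (z, y, x)
  k <- k / sum(k)
  psf_model(k, voxel_spacing, form = "gaussian",
            sigma_lateral = sigma_lateral, sigma_axial = sig_ax,
            depth_coeff = depth_coeff)
}

# kernel resampled/validated for a target voxel spacing
psf_kernel_at <- function(psf, voxel_spacing) {
  stopifnot(inherits(psf, "psf_model"))
  if (max(abs(psf$spacing - voxel_spacing)) < 1e-9) return(psf$kernel)
  if (psf$form == "gaussian")
    return(theoretical_psf(psf$sigma_lateral, psf$sigma_axial, voxel_spacing)$kernel)
  stop("empirical PSF was sampled at a different voxel spacing")
}

# small separable Gaussian smoothing in voxel units, used to regularize the
# level set before isosurfacing (removes the jagged-surface area bias of
# meshing a near-binary field). Support shrinks to fit small crops.
gaussian_smooth_voxels <- function(x, sigma_vox) {
  if (sigma_vox <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma_vox))
  r <- min(r, floor((min(dim(x)) - 1) / 2))
  if (r < 1L) return(x)
  i <- (-r):r
  w <- exp(-i^2 / (2 * sigma_vox^2))
  w <- w / sum(w)
  convolve_fft(x, outer(outer(w, w), w))
}

# periodic-boundary FFT convolution of a (z,y,x) volume with a centred,
# odd-dimension kernel. Exactly flux-preserving for a normalized kernel.
convolve_fft <- function(x, kernel) {
  dx <- dim(x); dk <- dim(kernel)
  if (any(dk > dx)) stop("kernel larger than the volume on some axis")
  kpad <- array(0, dx)
  ctr <- (dk + 1) / 2
  idx <- lapply(1:3, function(a) ((seq_len(dk[a]) - ctr[a] - 1) %% dx[a]) + 1)
  kpad[idx[[1]], idx[[2]], idx[[3]]] <- kernel
  out <- Re(fft(fft(x) * fft(kpad), inverse = TRUE)) / length(x)
  # non-negative inputs and kernel: negatives are FFT round-off
  out[out < 0] <- 0
  out
}

#' Richardson-Lucy deconvolution
#'
#' Iterative maximum-likelihood restoration under Poisson noise, the open
#' standard counterpart of commercial CMLE deconvolution. The update
#' multiplies the current estimate by the back-projected ratio of observed to
#' re-blurred intensities, so the output is non-negative by construction and,
#' with a normalized PSF and periodic boundaries, total intensity is
#' conserved. A spatially constant image is a fixed point.
#'
#' @param grid A [voxel_grid()] or a 3D array.
#' @param psf A normalized [psf_model()].
#' @param iterations Number of RL iterations (default 40).
#' @param channels Channels to deconvolve (default: all).
#' @return Same type as `grid`, with attribute `rl_iterations` recording the
#'   iteration count.
#' @export
richardson_lucy_deconvolve <- function(grid, psf, iterations = 40L, channels = NULL) {
  stopifnot(inherits(psf, "psf_model"))
  if (iterations < 1) stop("iterations must be >= 1")
  if (abs(sum(psf$kernel) - 1) > 1e-6) stop("PSF must be normalized (kernel sums to 1)")
  is_grid <- inherits(grid, "voxel_grid")
  spacing <- if (is_grid) grid$spacing else psf$spacing
  kern <- psf_kernel_at(psf, spacing)
  rl_one <- function(obs) {
    dx <- dim(obs); dk <- dim(kern)
    kpad <- array(0, dx)
    ctr <- (dk + 1) / 2
    idx <- lapply(1:3, function(a) ((seq_len(dk[a]) - ctr[a] - 1) %% dx[a]) + 1)
    kpad[idx[[1]], idx[[2]], idx[[3]]] <- kern
    otf <- fft(kpad)
    n <- length(obs)
    eps <- 1e-12 * max(obs)
    if (eps == 0) return(obs)
    est <- obs
    for (it in seq_len(iterations)) {
      blur <- Re(fft(fft(est) * otf, inverse = TRUE)) / n
      ratio <- obs / pmax(blur, eps)
      corr <- Re(fft(fft(ratio) * Conj(otf), inverse = TRUE)) / n
      est <- est * corr
      est[est < 0] <- 0
    }
    est
  }
  if (is_grid) {
    chs <- if (is.null(channels)) names(grid$data) else channels
    for (ch in chs) grid$data[[ch]] <- rl_one(grid$data[[ch]])
    attr(grid, "rl_iterations") <- as.integer(iterations)
    grid
  } else {
    out <- rl_one(grid)
    attr(out, "rl_iterations") <- as.integer(iterations)
    out
  }
}

#' Estimate the point-spread function from a bead control image
#'
#' Fits an anisotropic Gaussian to each isolated bead by intensity-weighted
#' second moments and corrects for the finite bead size by quadrature
#' subtraction: a uniform sphere of radius R has per-axis variance R^2 / 5,
#' and variances add under convolution, so `sigma_psf^2 = sigma_meas^2 -
#' R^2 / 5` exactly, independent of the bead profile shape. Beads touching
#' the volume border or closer than twice the bead diameter to a neighbour
#' (unresolvable, "merged") are excluded. The estimate is invariant to
#' global intensity scaling.
#'
#' @param bead_image A [voxel_grid()] (first channel used) or 3D array plus
#'   `spacing`.
#' @param known_diameter Physical bead diameter in um.
#' @param threshold Threshold spec for bead detection (see
#'   [segment_granules()]); default 30% of the image maximum.
#' @param spacing Required when `bead_image` is a bare array.
#' @return A Gaussian [psf_model()] with attributes `n_beads` and
#'   `bead_fits` (per-bead sigma table).
#' @export
estimate_psf_from_beads <- function(bead_image, known_diameter,
                                    threshold = "frac:0.3", spacing = NULL) {
  if (inherits(bead_image, "voxel_grid")) {
    vol <- bead_image$data[[1]]
    spacing <- bead_image$spacing
  } else {
    vol <- bead_image
    if (is.null(spacing)) stop("`spacing` required for array input")
  }
  if (known_diameter <= 0) stop("known_diameter must be > 0")
  if (max(vol) <= 0) stop("no beads detectable: image is empty")
  th <- resolve_threshold(vol, threshold)
  mask <- vol > th
  if (!any(mask)) stop("no beads detectable above threshold")
  dims <- dim(vol)
  lab <- cc_label_3d(as.vector(mask), dims, 26L)
  ncomp <- attr(lab, "n_components")
  if (ncomp < 1) stop("no beads detectable above threshold")
  lab <- array(lab, dims)
  cents <- matrix(NA_real_, ncomp, 3)
  keep <- rep(TRUE, ncomp)
  bbox <- vector("list", ncomp)
  for (l in seq_len(ncomp)) {
    w <- which(lab == l, arr.ind = TRUE)
    bbox[[l]] <- rbind(apply(w, 2, min), apply(w, 2, max))
    if (any(bbox[[l]][1, ] == 1L) || any(bbox[[l]][2, ] == dims)) keep[l] <- FALSE
    wt <- vol[w]
    cents[l, ] <- c(sum(w[, 3] * wt), sum(w[, 2] * wt), sum(w[, 1] * wt)) / sum(wt)
    cents[l, ] <- (cents[l, ] - 1) * spacing        # (x, y, z) um
  }
  if (ncomp > 1) {
    dd <- as.matrix(dist(cents)); diag(dd) <- Inf
    keep <- keep & (apply(dd, 1, min) >= 2 * known_diameter)
  }
  usable <- which(keep)
  if (length(usable) < 3)
    stop("need >= 3 isolated beads for PSF estimation, found ", length(usable))
  var_bead <- (known_diameter / 2)^2 / 5
  fits <- lapply(usable, function(l) {
    b <- bbox[[l]]
    half <- pmax(ceiling((b[2, ] - b[1, ]) * 0.75), 4L)
    lo <- pmax(b[1, ] - half, 1L); hi <- pmin(b[2, ] + half, dims)
    crop <- vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    w <- pmax(crop - min(crop), 0)
    idx <- which(w > 0, arr.ind = TRUE)
    wt <- w[idx]; wt <- wt / sum(wt)
    pos <- cbind((idx[, 3] + lo[3] - 2) * spacing[1],
                 (idx[, 2] + lo[2] - 2) * spacing[2],
                 (idx[, 1] + lo[1] - 2) * spacing[3])
    mu <- colSums(pos * wt)
    v <- colSums((pos - rep(mu, each = nrow(pos)))^2 * wt)
    c(vx = v[1], vy = v[2], vz = v[3])
  })
  V <- do.call(rbind, fits)
  v_lat <- mean(c(V[, 1], V[, 2])) - var_bead
  v_ax <- mean(V[, 3]) - var_bead
  if (v_lat <= 0 || v_ax <= 0)
    stop("bead larger than measured spread: corrected sigma^2 is non-positive")
  sig_lat <- sqrt(v_lat); sig_ax <- sqrt(v_ax)
  out <- theoretical_psf(sig_lat, max(sig_ax, sig_lat), voxel_spacing = spacing)
  attr(out, "n_beads") <- length(usable)
  attr(out, "bead_fits") <- tibble::tibble(
    bead = usable,
    sigma_x = sqrt(pmax(V[, 1] - var_bead, 0)),
    sigma_y = sqrt(pmax(V[, 2] - var_bead, 0)),
    sigma_z = sqrt(pmax(V[, 3] - var_bead, 0))
  )
  out
}
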