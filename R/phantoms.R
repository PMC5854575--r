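#' Confocal noise model for phantom generation
#'
#' Standard confocal acquisition noise: Poisson shot noise on the photon
#' counts plus additive Gaussian read noise. The rendered intensity is
#' multiplied by `photon_scale` to give the expected photon count of each
#' voxel; the returned image is in count units, clamped at zero.
#'
#' @param photon_scale Expected photons per unit rendered intensity (>= 0).
#' @param read_sd Standard deviation of additive Gaussian read noise, counts.
#' @param seed Optional integer seed; a fixed seed makes every phantom that
#'   uses this model bit-identical between runs.
#' @return A `noise_model` object.
#' @export
noise_model <- function(photon_scale = 100, read_sd = 0, seed = NULL) {
  stopifnot(photon_scale >= 0, read_sd >= 0)
  structure(list(photon_scale = photon_scale, read_sd = read_sd, seed = seed),
            class = "noise_model")
}

apply_noise <- function(arr, noise) {
  if (is.null(noise)) return(arr)
  stopifnot(inherits(noise, "noise_model"))
  out <- arr <- pmax(arr, 0)
  if (noise$photon_scale > 0) {
    out <- array(rpois(length(arr), lambda = arr * noise$photon_scale), dim(arr))
  }
  if (noise$read_sd > 0) out <- out + rnorm(length(out), 0, noise$read_sd)
  out[out < 0] <- 0
  out
}

# evaluate `code` under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# render one shape additively into `vol` ((z,y,x) array). Voxel value is the
# analytic inside-fraction approximated by supersample^3 subsamples times the
# shape intensity; anti-aliasing removes the systematic volume bias of binary
# voxelization.
render_into <- function(vol, spec, spacing, supersample = 2L) {
  dims <- dim(vol)                       # (nz, ny, nx)
  sx <- spacing[1]; sy <- spacing[2]; sz <- spacing[3]
  he <- shape_half_extents(spec)
  ctr <- spec$center
  lims <- c((dims[3] - 1) * sx, (dims[2] - 1) * sy, (dims[1] - 1) * sz)
  for (ax in 1:3) {
    lo <- ctr[ax] - he[ax]; hi <- ctr[ax] + he[ax]
    if (lo < 0 || hi > lims[ax])
      stop(sprintf("shape extent [%.3f, %.3f] um exceeds grid bounds [0, %.3f] um on the %s axis",
                   lo, hi, lims[ax], c("x", "y", "z")[ax]))
  }
  pad <- 1L
  kx <- max(1L, floor((ctr[1] - he[1]) / sx) + 1L - pad):min(dims[3], ceiling((ctr[1] + he[1]) / sx) + 1L + pad)
  jy <- max(1L, floor((ctr[2] - he[2]) / sy) + 1L - pad):min(dims[2], ceiling((ctr[2] + he[2]) / sy) + 1L + pad)
  iz <- max(1L, floor((ctr[3] - he[3]) / sz) + 1L - pad):min(dims[1], ceiling((ctr[3] + he[3]) / sz) + 1L + pad)
  m <- as.integer(supersample)
  offs <- (seq_len(m) - (m + 1) / 2) / m
  fine <- function(idx, s, cc) as.vector(outer(offs * s, (idx - 1) * s - cc, "+"))
  fx <- fine(kx, sx, ctr[1]); fy <- fine(jy, sy, ctr[2]); fz <- fine(iz, sz, ctr[3])
  F <- shape_frame(spec$orientation)
  # local coords as (z,y,x)-ordered 3D arrays via nested outer sums
  loc <- function(row) {
    zy <- outer(fz * F[row, 3], fy * F[row, 2], "+")
    outer(zy, fx * F[row, 1], "+")
  }
  inside <- shape_inside_local(spec, loc(1), loc(2), loc(3))
  dim(inside) <- c(m, length(iz), m, length(jy), m, length(kx))
  inside <- aperm(inside, c(1, 3, 5, 2, 4, 6))
  dim(inside) <- c(m^3, length(iz) * length(jy) * length(kx))
  frac <- colMeans(inside)
  dim(frac) <- c(length(iz), length(jy), length(kx))
  vol[iz, jy, kx] <- vol[iz, jy, kx] + frac * spec$intensity
  vol
}

granule_truth_row <- function(id, spec, nucleus_distance = NA_real_,
                              normalized_height = NA_real_) {
  tibble::tibble(
    id = id,
    kind = spec$kind,
    center_x = spec$center[1], center_y = spec$center[2], center_z = spec$center[3],
    volume_um3 = shape_volume(spec),
    area_um2 = shape_area(spec),
    extent_um = shape_extent(spec),
    size_class = ifelse(shape_extent(spec) > 3, "aggregate", "single"),
    nucleus_distance_um = nucleus_distance,
    normalized_height = normalized_height
  )
}

#' Render a single analytic shape into a voxel grid
#'
#' @param spec A [shape_spec()].
#' @param voxel_spacing `c(dx, dy, dz)` um.
#' @param grid_shape Array dimensions `c(nz, ny, nx)`.
#' @param supersample Sub-voxel sampling factor per axis for anti-aliased
#'   occupancy (default 2).
#' @return A list with `grid` (single-channel [voxel_grid()]) and `truth`
#'   (one-row ground-truth tibble with closed-form volume, area and extent).
#' @examples
#' sp <- shape_spec("sphere", center = c(1.5, 1.5, 1.5), size = list(radius = 0.5))
#' ph <- render_shape(sp, c(0.1, 0.1, 0.1), c(31, 31, 31))
#' sum(get_channel(ph$grid)) * 0.1^3  # ~ 4/3 * pi * 0.5^3
#' @export
render_shape <- function(spec, voxel_spacing, grid_shape, supersample = 2L) {
  stopifnot(inherits(spec, "shape_spec"), all(voxel_spacing > 0))
  vol <- array(0, grid_shape)
  vol <- render_into(vol, spec, voxel_spacing, supersample)
  list(grid = voxel_grid(vol, voxel_spacing), truth = granule_truth_row(1L, spec))
}

# analytic signed distance from point p to the surface of a nucleus shape
# (negative inside); exact for spheres, numeric surface search for ellipsoids
analytic_nucleus_distance <- function(p, nucleus_spec) {
  if (is.null(nucleus_spec)) return(NA_real_)
  d <- p - nucleus_spec$center
  if (nucleus_spec$kind == "sphere")
    return(sqrt(sum(d^2)) - nucleus_spec$size$radius)
  if (nucleus_spec$kind == "ellipsoid") {
    F <- shape_frame(nucleus_spec$orientation)
    l <- as.vector(F %*% d)
    ax <- c(nucleus_spec$size$a, nucleus_spec$size$b, nucleus_spec$size$c)
    surf_dist <- function(ang) {
      s <- c(cos(ang[1]) * ax[1],
             sin(ang[1]) * cos(ang[2]) * ax[2],
             sin(ang[1]) * sin(ang[2]) * ax[3])
      min(sum((l - s)^2), sum((l + s)^2))
    }
    starts <- list(c(pi / 4, pi / 4), c(pi / 2, 0), c(pi / 4, 3 * pi / 4),
                   c(3 * pi / 4, pi / 4), c(pi / 2, pi / 2))
    best <- min(vapply(starts, function(s0)
      optim(s0, surf_dist, method = "Nelder-Mead")$value, numeric(1)))
    inside <- sum((l / ax)^2) <= 1
    return(if (inside) -sqrt(best) else sqrt(best))
  }
  NA_real_
}

#' Compose a single-cell phantom: granule and nucleus channels
#'
#' Renders a list of granule shapes and (optionally) a nucleus shape into a
#' two-channel volume, convolves each channel with the point-spread function
#' and applies acquisition noise — emulating a fixed-keratinocyte confocal
#' stack with exact analytic ground truth. The truth table records each
#' granule's closed-form geometry and the analytic signed distance from its
#' centroid to the nucleus surface (negative inside the nucleus).
#'
#' @param granule_specs List of [shape_spec()] (may be empty).
#' @param nucleus_spec A sphere or ellipsoid [shape_spec()], or `NULL` for a
#'   granule-only phantom.
#' @param voxel_spacing `c(dx, dy, dz)` um.
#' @param grid_shape `c(nz, ny, nx)`.
#' @param psf A [psf_model()] or `NULL` for an ideal (delta) PSF.
#' @param noise A [noise_model()] or `NULL` for noiseless rendering.
#' @param supersample Anti-aliasing factor, see [render_shape()].
#' @return List with `grid` (channels `granules`, `nucleus`) and `truth`
#'   (one row per granule).
#' @export
compose_cell_phantom <- function(granule_specs, nucleus_spec = NULL,
                                 voxel_spacing, grid_shape,
                                 psf = NULL, noise = NULL, supersample = 2L) {
  if (!is.null(psf) && !inherits(psf, "psf_model")) stop("`psf` must be a psf_model or NULL")
  gr <- array(0, grid_shape)
  for (spec in granule_specs) gr <- render_into(gr, spec, voxel_spacing, supersample)
  nuc <- array(0, grid_shape)
  if (!is.null(nucleus_spec)) {
    if (!nucleus_spec$kind %in% c("sphere", "ellipsoid"))
      stop("nucleus_spec must be a sphere or an ellipsoid")
    nuc <- render_into(nuc, nucleus_spec, voxel_spacing, supersample)
  }
  if (!is.null(psf)) {
    k <- psf_kernel_at(psf, voxel_spacing)
    gr <- convolve_fft(gr, k)
    nuc <- convolve_fft(nuc, k)
  }
  seed <- if (!is.null(noise)) noise$seed else NULL
  res <- with_seed(seed, {
    list(gr = apply_noise(gr, noise), nuc = apply_noise(nuc, noise))
  })
  truth <- if (length(granule_specs)) {
    do.call(rbind, lapply(seq_along(granule_specs), function(i)
      granule_truth_row(i, granule_specs[[i]],
        nucleus_distance = analytic_nucleus_distance(granule_specs[[i]]$center, nucleus_spec))))
  } else granule_truth_row(1L, shape_spec("sphere", c(0, 0, 0) + 1, list(radius = 1)))[0, ]
  list(
    grid = voxel_grid(list(granules = res$gr, nucleus = res$nuc), voxel_spacing),
    truth = truth
  )
}

#' Compose an epidermal-sheet phantom with height gradients
#'
#' Emulates an epidermis stack in which granule density and elongation change
#' with normalized height (0 = basal side at `z = 0`, 1 = outermost layer):
#' granule heights are drawn from `density_gradient` by rejection sampling,
#' small granules are elongated according to `shape_gradient`, and a fraction
#' `aggregate_fraction` of objects are rendered as aggregates longer than the
#' 3-um size-class cutoff. The truth table always carries the exact drawn
#' geometry and normalized heights; rendering into a voxel volume is optional
#' so large populations can be studied at table level only.
#'
#' @param layer_count Number of height bins recorded in the truth table (>= 2).
#' @param density_gradient Function of normalized height in `[0, 1]` giving
#'   relative granule density (monotone for a differentiation gradient).
#' @param shape_gradient Function of normalized height giving an elongation
#'   factor (1 = round) for the small-granule population.
#' @param aggregate_fraction Probability that an object is an aggregate
#'   (length > 3 um).
#' @param n_granules Number of granules to draw.
#' @param voxel_spacing,grid_shape Volume geometry (used when `render = TRUE`).
#' @param psf,noise Optional [psf_model()] / [noise_model()].
#' @param render If `FALSE`, return only the ground-truth table.
#' @param seed Optional integer seed for the object draw.
#' @return List with `truth` (tibble; columns as [render_shape()] plus
#'   `normalized_height` and `height_bin`) and `grid` (or `NULL`).
#' @export
compose_epidermis_phantom <- function(layer_count = 5,
                                      density_gradient = function(h) 0.25 + 0.75 * h,
                                      shape_gradient = function(h) 1 + 1.5 * h,
                                      aggregate_fraction = 0.045,
                                      n_granules = 200,
                                      voxel_spacing = c(0.15, 0.15, 0.15),
                                      grid_shape = c(72, 160, 160),
                                      psf = NULL, noise = NULL,
                                      render = TRUE, seed = NULL) {
  if (layer_count < 2) stop("layer_count must be >= 2")
  stopifnot(aggregate_fraction >= 0, aggregate_fraction <= 1, n_granules >= 1)
  H <- (grid_shape[1] - 1) * voxel_spacing[3]
  lim_x <- (grid_shape[3] - 1) * voxel_spacing[1]
  lim_y <- (grid_shape[2] - 1) * voxel_spacing[2]
  dmax <- max(vapply(seq(0, 1, length.out = 201), density_gradient, numeric(1)))
  if (dmax <= 0) stop("density_gradient must be positive somewhere on [0, 1]")
  specs <- vector("list", n_granules)
  hts <- numeric(n_granules)
  with_seed(seed, {
    for (i in seq_len(n_granules)) {
      repeat {
        h <- runif(1)
        if (runif(1) < density_gradient(h) / dmax) break
      }
      if (runif(1) < aggregate_fraction) {
        r <- runif(1, 0.3, 0.45)
        len <- runif(1, 3.3, 4.5)
        spec0 <- list(kind = "capsule",
                      size = list(half_length = len / 2 - r, radius = r),
                      orient_inplane = TRUE)
      } else {
        e <- max(1, shape_gradient(h))
        r <- runif(1, 0.3, 0.45)
        hl <- min(0.75 * (e - 1) * r, 1.35 - r)
        if (hl < 0.05) {
          spec0 <- list(kind = "sphere", size = list(radius = r), orient_inplane = FALSE)
        } else {
          spec0 <- list(kind = "capsule", size = list(half_length = hl, radius = r),
                        orient_inplane = TRUE)
        }
      }
      phi <- runif(1, 0, 2 * pi)
      ori <- if (spec0$orient_inplane) c(cos(phi), sin(phi), 0) else c(0, 0, 1)
      tmp <- shape_spec(spec0$kind, c(0, 0, 0) + 99, spec0$size, orientation = ori)
      he <- shape_half_extents(tmp)
      z <- min(max(h * H, he[3]), H - he[3])
      ctr <- c(runif(1, he[1], lim_x - he[1]), runif(1, he[2], lim_y - he[2]), z)
      specs[[i]] <- shape_spec(spec0$kind, ctr, spec0$size, orientation = ori)
      hts[i] <- z / H
    }
  })
  truth <- do.call(rbind, lapply(seq_len(n_granules), function(i)
    granule_truth_row(i, specs[[i]], normalized_height = hts[i])))
  truth$height_bin <- pmin(layer_count, 1L + floor(truth$normalized_height * layer_count))
  grid <- NULL
  if (render) {
    vol <- array(0, grid_shape)
    for (spec in specs) vol <- render_into(vol, spec, voxel_spacing)
    if (!is.null(psf)) vol <- convolve_fft(vol, psf_kernel_at(psf, voxel_spacing))
    vol <- with_seed(if (!is.null(noise)) noise$seed else NULL, apply_noise(vol, noise))
    grid <- voxel_grid(list(granules = vol), voxel_spacing)
  }
  list(grid = grid, truth = truth, specs = specs)
}

#' Sample a random, non-overlapping granule population
#'
#' Draws shape specifications spanning the observed granule morphologies
#' (round, elongated, ring) with random orientations, placed without overlap
#' (disjoint bounding spheres) inside a rectangular region. Singles stay
#' well below the 3-um aggregate cutoff and aggregates well above it, so the
#' drawn size class is unambiguous. Used for parameter-recovery studies
#' against the closed-form truth.
#'
#' @param n Number of granules.
#' @param region_um Physical region `c(x, y, z)` extents in um.
#' @param kinds Shape kinds to draw from.
#' @param aggregate_fraction Probability of drawing an aggregate-sized
#'   capsule (length 3.3-4.7 um).
#' @param min_separation Minimum gap between bounding spheres, um.
#' @param seed Optional integer seed.
#' @param max_tries Placement attempts per granule before giving up.
#' @return List of [shape_spec()].
#' @export
sample_granule_specs <- function(n, region_um,
                                 kinds = c("sphere", "ellipsoid", "capsule", "torus"),
                                 aggregate_fraction = 0, min_separation = 0.3,
                                 seed = NULL, max_tries = 5000L) {
  draw_one <- function(is_aggregate) {
    if (is_aggregate) {
      r <- runif(1, 0.45, 0.5)
      return(shape_spec("capsule", c(0, 0, 0) + 99, # centre set at placement
                        list(half_length = runif(1, 1.3, 1.9), radius = r),
                        orientation = random_unit()))
    }
    # minimum feature sizes keep every extent above the 0.2/0.8 um
    # lateral/axial sampling limits, whatever the orientation
    kind <- sample(kinds, 1)
    sz <- switch(kind,
      sphere = list(radius = runif(1, 0.45, 0.6)),
      ellipsoid = {
        a <- runif(1, 0.6, 0.85)
        list(a = a, b = runif(1, 0.45, 0.55), c = runif(1, 0.45, 0.55))
      },
      capsule = list(half_length = runif(1, 0.5, 0.9), radius = runif(1, 0.45, 0.5)),
      torus = list(major = runif(1, 0.65, 0.95), minor = runif(1, 0.45, 0.5))
    )
    shape_spec(kind, c(0, 0, 0) + 99, sz, orientation = random_unit())
  }
  random_unit <- function() {
    v <- rnorm(3)
    v / sqrt(sum(v^2))
  }
  with_seed(seed, {
    specs <- list()
    centers <- matrix(numeric(0), 0, 3)
    bounds <- numeric(0)
    for (i in seq_len(n)) {
      # the size-class decision is made once per granule; placement retries
      # only redraw geometry, so thin regions cannot bias the class mix
      is_agg <- runif(1) < aggregate_fraction
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        cand <- draw_one(is_agg)
        b <- shape_bound(cand)
        he <- shape_half_extents(cand)   # wall margins respect orientation
        if (any(2 * he + 0.2 >= region_um)) next
        ctr <- c(runif(1, he[1] + 0.1, region_um[1] - he[1] - 0.1),
                 runif(1, he[2] + 0.1, region_um[2] - he[2] - 0.1),
                 runif(1, he[3] + 0.1, region_um[3] - he[3] - 0.1))
        if (nrow(centers)) {
          dd <- sqrt(rowSums(sweep(centers, 2, ctr)^2))
          if (any(dd < bounds + b + min_separation)) next
        }
        cand$center <- ctr
        specs[[i]] <- cand
        centers <- rbind(centers, ctr)
        bounds <- c(bounds, b)
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place granule ", i, "; enlarge the region or reduce n")
    }
    specs
  })
}

#' Bead-in-gel control phantom
#'
#' A sparse field of identical fluorescent spheres, the synthetic equivalent
#' of the 1-um bead-in-polyacrylamide control used to characterise the
#' imaging system: the known diameter makes the rendered, blurred and
#' deconvolved extents directly comparable. Beads whose centres lie closer
#' than twice the lateral PSF sigma (or one diameter, for a delta PSF) are
#' flagged `merged` in the truth table, since they cannot be resolved.
#'
#' @param bead_diameter Bead diameter in um (must exceed twice the lateral
#'   voxel spacing).
#' @param voxel_spacing `c(dx, dy, dz)` um.
#' @param psf,noise Optional [psf_model()] / [noise_model()].
#' @param n_beads Number of beads when `positions` is `NULL`.
#' @param positions Optional n x 3 matrix of centres (um).
#' @param grid_shape Optional `c(nz, ny, nx)`; auto-sized when `NULL`.
#' @return List with `grid`, `truth` (adds a `merged` logical column).
#' @export
make_bead_phantom <- function(bead_diameter = 1, voxel_spacing = c(0.05, 0.05, 0.05),
                              psf = NULL, noise = NULL, n_beads = 5,
                              positions = NULL, grid_shape = NULL) {
  if (bead_diameter <= 2 * max(voxel_spacing[1:2]))
    stop("bead diameter must exceed twice the lateral voxel spacing")
  r <- bead_diameter / 2
  sig_lat <- if (!is.null(psf) && psf$form == "gaussian") psf$sigma_lateral else 0
  sig_ax <- if (!is.null(psf) && psf$form == "gaussian") psf$sigma_axial else 0
  margin <- r + 4 * max(sig_lat, sig_ax) + 2 * max(voxel_spacing)
  if (is.null(positions)) {
    sep <- 2 * bead_diameter + 8 * sig_lat
    positions <- cbind(margin + sep * (seq_len(n_beads) - 1), margin, margin)
  }
  positions <- matrix(positions, ncol = 3)
  if (is.null(grid_shape)) {
    ext <- apply(positions, 2, max) + margin
    grid_shape <- c(ceiling(ext[3] / voxel_spacing[3]) + 1,
                    ceiling(ext[2] / voxel_spacing[2]) + 1,
                    ceiling(ext[1] / voxel_spacing[1]) + 1)
  }
  vol <- array(0, grid_shape)
  specs <- apply(positions, 1, function(p)
    shape_spec("sphere", p, list(radius = r)), simplify = FALSE)
  for (spec in specs) vol <- render_into(vol, spec, voxel_spacing)
  if (!is.null(psf)) vol <- convolve_fft(vol, psf_kernel_at(psf, voxel_spacing))
  vol <- with_seed(if (!is.null(noise)) noise$seed else NULL, apply_noise(vol, noise))
  truth <- do.call(rbind, lapply(seq_along(specs), function(i) granule_truth_row(i, specs[[i]])))
  merge_limit <- if (sig_lat > 0) 2 * sig_lat else bead_diameter
  dd <- as.matrix(dist(positions)); diag(dd) <- Inf
  truth$merged <- unname(apply(dd, 1, min) < merge_limit)
  truth$diameter_um <- bead_diameter
  list(grid = voxel_grid(list(beads = vol), voxel_spacing), truth = truth)
}

#' Two-channel LAURDAN phantom with a known GP mixture
#'
#' Generates the 440-nm and 490-nm emission-band channels of a generalized
#' polarization (GP) image. Each labelled region of `region_map` draws
#' per-pixel GP values `g` from a Gaussian (clamped to `[-1, 1]`), and the
#' band intensities solve `I440 = T (1 + g) / 2`, `I490 = T (1 - g) / 2`, so
#' recomputing GP from the noiseless channels returns the drawn `g` exactly.
#'
#' @param region_map Integer array (2D or 3D), 0 = background.
#' @param gp_means,gp_sds Per-region GP mean (in `[-1, 1]`) and sd, ordered
#'   by sorted region label.
#' @param total_intensity Per-pixel total band intensity `T` (arbitrary units).
#' @param noise Optional [noise_model()] applied to each band.
#' @param seed Optional integer seed for the GP draw.
#' @param voxel_spacing Spacing metadata for the output grid.
#' @return List with `grid` (channels `I440`, `I490`), `truth` (per-region
#'   tibble) and `gp_true` (array of drawn GP values, NA outside regions).
#' @export
make_gp_phantom <- function(region_map, gp_means, gp_sds, total_intensity = 1000,
                            noise = NULL, seed = NULL,
                            voxel_spacing = c(1, 1, 1)) {
  rm3 <- region_map
  if (length(dim(rm3)) == 2L || is.null(dim(rm3)))
    rm3 <- array(rm3, c(1, dim(as.matrix(region_map))))
  regions <- sort(unique(as.vector(rm3[rm3 > 0])))
  if (length(gp_means) != length(regions) || length(gp_sds) != length(regions))
    stop("need one gp_mean and gp_sd per region (", length(regions), " regions)")
  if (any(gp_means < -1 | gp_means > 1)) stop("gp_means must lie in [-1, 1]")
  g <- array(NA_real_, dim(rm3))
  with_seed(seed, {
    for (i in seq_along(regions)) {
      idx <- which(rm3 == regions[i])
      gi <- rnorm(length(idx), gp_means[i], gp_sds[i])
      g[idx] <- pmin(pmax(gi, -1), 1)
    }
  })
  tot <- ifelse(is.na(g), 0, total_intensity)
  gz <- ifelse(is.na(g), 0, g)
  i440 <- tot * (1 + gz) / 2
  i490 <- tot * (1 - gz) / 2
  if (!is.null(noise)) {
    res <- with_seed(noise$seed, list(a = apply_noise(i440, noise), b = apply_noise(i490, noise)))
    i440 <- res$a; i490 <- res$b
  }
  truth <- do.call(rbind, lapply(seq_along(regions), function(i) {
    gi <- g[rm3 == regions[i]]
    tibble::tibble(region = regions[i], n_pixels = length(gi),
                   gp_mean = gp_means[i], gp_sd = gp_sds[i],
                   drawn_mean = mean(gi), drawn_sd = sd(gi))
  }))
  list(grid = voxel_grid(list(I440 = i440, I490 = i490), voxel_spacing),
       truth = truth, gp_true = g)
}
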