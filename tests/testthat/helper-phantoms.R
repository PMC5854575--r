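# shared fixtures, built in code at test time

iso_spacing <- function(s) c(s, s, s)

# finely sampled unit-intensity sphere phantom
sphere_phantom <- function(radius = 1, s = 0.05, center = NULL) {
  n <- ceiling(2 * (radius + 5 * s) / s) + 1
  if (is.null(center)) center <- rep((n - 1) * s / 2, 3)
  spec <- shape_spec("sphere", center, list(radius = radius))
  list(spec = spec, phantom = render_shape(spec, iso_spacing(s), c(n, n, n)))
}

# brute-force signed distance oracle: nearest surface voxel centre
brute_force_nucleus_distance <- function(p, nucleus) {
  mask <- nucleus$mask
  sp <- nucleus$spacing
  surf <- khgmorph:::nucleus_surface_mask(mask)
  idx <- which(surf, arr.ind = TRUE)               # (z, y, x)
  pos <- cbind((idx[, 3] - 1) * sp[1], (idx[, 2] - 1) * sp[2], (idx[, 1] - 1) * sp[3])
  d <- sqrt(min(rowSums(sweep(pos, 2, p)^2)))
  ijk <- cbind(round(p[3] / sp[3]) + 1, round(p[2] / sp[2]) + 1, round(p[1] / sp[1]) + 1)
  if (mask[ijk]) -d else d
}

# centroid-matched parameter-recovery errors on a rendered population
recovery_errors <- function(n_batches = 4, per_batch = 25, spacing = 0.05,
                            seed0 = 100, aggregate_fraction = 0.1) {
  out <- list()
  for (b in seq_len(n_batches)) {
    specs <- sample_granule_specs(per_batch, c(10, 10, 5) * sqrt(per_batch / 10),
                                  aggregate_fraction = aggregate_fraction,
                                  seed = seed0 + b)
    dims <- c(ceiling(5 * sqrt(per_batch / 10) / spacing) + 1,
              ceiling(10 * sqrt(per_batch / 10) / spacing) + 1,
              ceiling(10 * sqrt(per_batch / 10) / spacing) + 1)
    ph <- compose_cell_phantom(specs, NULL, voxel_spacing = iso_spacing(spacing),
                               grid_shape = dims)
    objs <- segment_granules(ph$grid, threshold = 0.5, channel = "granules")
    rec <- granule_morphometry(ph$grid, objs)
    tru <- ph$truth
    m <- apply(cbind(rec$centroid_x_um, rec$centroid_y_um, rec$centroid_z_um), 1,
               function(p) which.min((tru$center_x - p[1])^2 +
                                     (tru$center_y - p[2])^2 +
                                     (tru$center_z - p[3])^2))
    out[[b]] <- data.frame(
      volume = rec$volume_um3 / tru$volume_um3[m] - 1,
      area = rec$area_um2 / tru$area_um2[m] - 1,
      length = rec$length_um / tru$extent_um[m] - 1,
      class_ok = rec$size_class == tru$size_class[m],
      n_truth = nrow(tru), n_found = nrow(rec))
  }
  do.call(rbind, out)
}
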