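#' Mesh volume and surface area
#'
#' Surface area is the sum of triangle areas; volume uses the divergence
#' theorem (sum of signed tetrahedra spanned by the origin and each
#' triangle), orientation-corrected to a positive value. Volume is only
#' defined for closed meshes.
#'
#' @param mesh An `iso_mesh`.
#' @return Named numeric `c(volume_um3, area_um2)`.
#' @examples
#' # unit cube: V = 1, A = 6 exactly
#' v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
#' f <- rbind(c(1,3,2), c(2,3,4), c(5,6,7), c(6,8,7), c(1,2,5), c(2,6,5),
#'            c(3,7,4), c(4,7,8), c(1,5,3), c(3,5,7), c(2,4,6), c(4,8,6))
#' mesh_geometry(khgmorph:::new_iso_mesh(v, f))
#' @export
mesh_geometry <- function(mesh) {
  stopifnot(inherits(mesh, "iso_mesh"))
  if (!mesh$closed) stop("mesh is not closed: volume is undefined")
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cr <- cbind((b[, 2] - a[, 2]) * (c_[, 3] - a[, 3]) - (b[, 3] - a[, 3]) * (c_[, 2] - a[, 2]),
              (b[, 3] - a[, 3]) * (c_[, 1] - a[, 1]) - (b[, 1] - a[, 1]) * (c_[, 3] - a[, 3]),
              (b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (c_[, 1] - a[, 1]))
  area <- sum(sqrt(rowSums(cr^2))) / 2
  vol <- abs(sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
                 a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
                 a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1]))) / 6
  c(volume_um3 = vol, area_um2 = area)
}

#' Surface area of any (possibly open) mesh
#' @param mesh An `iso_mesh`.
#' @return Area in um^2.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  u1 <- v[f[, 2], , drop = FALSE] - a
  u2 <- v[f[, 3], , drop = FALSE] - a
  cr <- cbind(u1[, 2] * u2[, 3] - u1[, 3] * u2[, 2],
              u1[, 3] * u2[, 1] - u1[, 1] * u2[, 3],
              u1[, 1] * u2[, 2] - u1[, 2] * u2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Principal-axis extents of a segmented object
#'
#' The object length is the largest extent of the bounding box oriented
#' along the principal axes of the voxel-coordinate covariance — the
#' "box enclosing the 3D isovolume" definition. The remaining two extents
#' are reported as axial width (the axis best aligned with z) and lateral
#' width. Each extent includes the projection of one voxel onto its axis, so
#' it measures the union of voxel cuboids rather than the centre point set.
#'
#' @param object A `segmented_object`.
#' @param spacing `c(dx, dy, dz)` um (defaults to the segmentation spacing
#'   when available via `attr(object, "spacing")`).
#' @return Named numeric `c(length_um, width_lateral_um, width_axial_um)`.
#' @export
principal_extents <- function(object, spacing) {
  stopifnot(inherits(object, "segmented_object"))
  vx <- object$voxels
  if (nrow(vx) < 2) stop("object must span at least 2 voxels")
  pos <- cbind((vx[, 3] - 1) * spacing[1], (vx[, 2] - 1) * spacing[2],
               (vx[, 1] - 1) * spacing[3])           # (x, y, z) um
  cen <- colMeans(pos)
  cpos <- sweep(pos, 2, cen)
  cv <- crossprod(cpos) / nrow(cpos)
  ev <- eigen(cv, symmetric = TRUE)
  axes <- ev$vectors                                 # columns, by decreasing variance
  proj <- cpos %*% axes
  vox_proj <- abs(t(axes)) %*% spacing               # voxel cuboid projected on each axis
  ext <- apply(proj, 2, function(p) diff(range(p))) + as.vector(vox_proj)
  degenerate <- ext <= as.vector(vox_proj) + 1e-12
  len_i <- which.max(ext)
  rest <- setdiff(1:3, len_i)
  zalign <- abs(axes[3, rest])
  ax_i <- rest[which.max(zalign)]
  lat_i <- rest[which.min(zalign)]
  out <- c(length_um = ext[len_i], width_lateral_um = ext[lat_i],
           width_axial_um = ext[ax_i])
  if (any(degenerate[c(lat_i, ax_i)]))
    attr(out, "degenerate") <- TRUE                  # collinear voxel set: one-voxel width substituted
  out
}

#' Sphericity
#'
#' The Wadell sphericity `Sph = pi^(1/3) * (6 V)^(2/3) / A`: the ratio of
#' the surface area of a sphere with the object's volume to the object's
#' actual surface area. Exactly 1 for an ideal sphere, < 1 for elongated or
#' ring-shaped objects. Set `literal_form = TRUE` for the variant
#' `pi^(1/3) * (6 V / A)^(2/3)`, which carries units of length^(2/3) and is
#' provided for comparison only.
#'
#' @param V_iso Volume in um^3 (> 0).
#' @param A_iso Surface area in um^2 (> 0).
#' @param literal_form Use the dimensional variant (default `FALSE`).
#' @return Dimensionless sphericity.
#' @examples
#' sphericity(4 * pi / 3, 4 * pi)  # 1
#' sphericity(1, 6)                # cube: (pi/6)^(1/3) ~ 0.806
#' @export
sphericity <- function(V_iso, A_iso, literal_form = FALSE) {
  if (any(V_iso <= 0) || any(A_iso <= 0))
    stop("volume and area must be positive")
  if (literal_form) return(pi^(1 / 3) * (6 * V_iso / A_iso)^(2 / 3))
  pi^(1 / 3) * (6 * V_iso)^(2 / 3) / A_iso
}

#' Length threshold separating single granules from aggregates (um)
#' @export
AGGREGATE_LENGTH_UM <- 3

#' Full morphometric descriptor set of one granule
#'
#' Combines the mesh-based volume and surface area, the principal-axis
#' extents, sphericity, the aspect ratios `AxRatio = length / axial width`
#' and `LaRatio = length / lateral width`, and the size class: objects
#' longer than 3 um are aggregates (fused or clustered granules), shorter
#' ones single granules.
#'
#' @param object A `segmented_object`.
#' @param mesh Its `iso_mesh`.
#' @param spacing `c(dx, dy, dz)` um.
#' @return One-row tibble (a granule record) with columns `label`,
#'   `centroid_x/y/z_um`, `volume_um3`, `area_um2`, `length_um`,
#'   `width_lateral_um`, `width_axial_um`, `sphericity`, `ax_ratio`,
#'   `la_ratio`, `size_class`.
#' @export
characterize_granule <- function(object, mesh, spacing) {
  geo <- mesh_geometry(mesh)
  ext <- principal_extents(object, spacing)
  tibble::tibble(
    label = object$label,
    centroid_x_um = object$centroid[1],
    centroid_y_um = object$centroid[2],
    centroid_z_um = object$centroid[3],
    volume_um3 = unname(geo["volume_um3"]),
    area_um2 = unname(geo["area_um2"]),
    length_um = unname(ext["length_um"]),
    width_lateral_um = unname(ext["width_lateral_um"]),
    width_axial_um = unname(ext["width_axial_um"]),
    sphericity = sphericity(geo["volume_um3"], geo["area_um2"]),
    ax_ratio = unname(ext["length_um"] / ext["width_axial_um"]),
    la_ratio = unname(ext["length_um"] / ext["width_lateral_um"]),
    size_class = if (ext["length_um"] > AGGREGATE_LENGTH_UM) "aggregate" else "single"
  )
}

#' Morphometry of every segmented granule in a volume
#'
#' Convenience wrapper: meshes each object at the segmentation threshold and
#' assembles the granule records into one table.
#'
#' @param grid The [voxel_grid()] the objects came from.
#' @param objects Result of [segment_granules()].
#' @param iso_level Iso level override (default: segmentation threshold).
#' @return Tibble with one granule record per object (see
#'   [characterize_granule()]).
#' @export
granule_morphometry <- function(grid, objects, iso_level = NULL) {
  spacing <- if (inherits(grid, "voxel_grid")) grid$spacing else attr(objects, "spacing")
  lm <- attr(objects, "label_map")
  rows <- lapply(objects, function(ob) {
    mesh <- extract_isosurface_mesh(ob, grid, iso_level = iso_level, label_map = lm)
    characterize_granule(ob, mesh, spacing)
  })
  do.call(rbind, rows)
}
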