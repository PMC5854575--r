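#' @title Threshold resolution
#' @description Threshold specs accepted across the segmentation functions:
#' a number (absolute intensity), `"otsu"` (automatic, Otsu's criterion on a
#' 256-level histogram), `"frac:<f>"` (fraction of the channel maximum) or
#' `"abs:<v>"`. Returns the absolute threshold value.
#' @param vol 3D intensity array.
#' @param spec Threshold specification.
#' @keywords internal
resolve_threshold <- function(vol, spec) {
  if (is.numeric(spec)) return(as.numeric(spec))
  if (is.list(spec)) {
    return(switch(spec$type,
      otsu = resolve_threshold(vol, "otsu"),
      abs = as.numeric(spec$value),
      frac = as.numeric(spec$value) * max(vol),
      stop("unknown threshold type: ", spec$type)))
  }
  if (identical(spec, "otsu")) {
    rng <- range(vol)
    if (diff(rng) == 0) return(rng[1])
    xn <- (as.vector(vol) - rng[1]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(matrix(xn, ncol = 1)), range = c(0, 1), levels = 256)
    return(rng[1] + th * diff(rng))
  }
  if (grepl("^frac:", spec)) return(as.numeric(sub("^frac:", "", spec)) * max(vol))
  if (grepl("^abs:", spec)) return(as.numeric(sub("^abs:", "", spec)))
  stop("unknown threshold spec: ", spec)
}

new_segmented_object <- function(label, voxels, centroid, channel, threshold) {
  structure(list(label = label, voxels = voxels, centroid = centroid,
                 n_voxels = nrow(voxels), channel = channel,
                 threshold = threshold),
            class = "segmented_object")
}

#' Segment granules from an intensity channel
#'
#' Voxels above the threshold are grouped into 26-connected components
#' (26-neighbourhoods avoid splitting thin diagonal tubes). Components whose
#' axis-aligned bounding box is smaller than the microscope's sampling limit
#' — by default 0.2 um laterally and 0.8 um axially, the diffraction-limited
#' confocal resolution — are discarded as unresolvable and counted in the
#' attached log. Objects are relabelled deterministically by centroid
#' (z, then y, then x).
#'
#' @param grid A [voxel_grid()] or 3D array (then `spacing` is required).
#' @param channel Channel to segment (default `"granules"` if present, else
#'   the first channel).
#' @param threshold Threshold spec, see [resolve_threshold()]; default Otsu.
#' @param min_extent_lateral,min_extent_axial Minimum bounding-box extents in
#'   um below which an object is discarded.
#' @param spacing `c(dx, dy, dz)` um for array input.
#' @return A list of `segmented_object`s, each with `label`, `voxels`
#'   (n x 3 `(z, y, x)` indices), `centroid` (intensity-weighted centre of
#'   mass, `(x, y, z)` um), `n_voxels`, `channel`, `threshold`. Attributes:
#'   `label_map` (integer array), `log` (threshold used, raw and filtered
#'   counts), `spacing`.
#' @export
segment_granules <- function(grid, channel = NULL, threshold = "otsu",
                             min_extent_lateral = 0.2, min_extent_axial = 0.8,
                             spacing = NULL) {
  if (inherits(grid, "voxel_grid")) {
    if (is.null(channel))
      channel <- if ("granules" %in% names(grid$data)) "granules" else 1L
    vol <- get_channel(grid, channel)
    spacing <- grid$spacing
  } else {
    vol <- grid
    if (is.null(spacing)) stop("`spacing` required for array input")
    if (is.null(channel)) channel <- "ch1"
  }
  th <- resolve_threshold(vol, threshold)
  dims <- dim(vol)
  empty <- function(n_raw = 0L, n_filt = 0L) {
    res <- list()
    attr(res, "label_map") <- array(0L, dims)
    attr(res, "log") <- list(threshold = th, n_raw = n_raw, n_filtered = n_filt)
    attr(res, "spacing") <- spacing
    res
  }
  if (th >= max(vol)) {
    if (max(vol) > 0) warning("threshold at or above the maximum intensity; no objects")
    return(empty())
  }
  mask <- vol > th
  if (!any(mask)) return(empty())
  lab <- cc_label_3d(as.vector(mask), dims, 26L)
  ncomp <- attr(lab, "n_components")
  lab <- array(lab, dims)
  idx <- which(lab > 0L)
  ai <- arrayInd(idx, dims)                      # (z, y, x)
  l <- lab[idx]
  wt <- vol[idx]
  ord <- order(l)
  ai <- ai[ord, , drop = FALSE]; l <- l[ord]; wt <- wt[ord]
  splits <- split(seq_along(l), l)
  objs <- list(); n_filt <- 0L
  for (s in splits) {
    vx <- ai[s, , drop = FALSE]
    ext <- (apply(vx, 2, max) - apply(vx, 2, min) + 1) * spacing_zyx(spacing)  # (z,y,x) um
    if (max(ext[2], ext[3]) < min_extent_lateral || ext[1] < min_extent_axial) {
      n_filt <- n_filt + 1L
      next
    }
    w <- wt[s]
    cen <- c(sum((vx[, 3] - 1) * w), sum((vx[, 2] - 1) * w), sum((vx[, 1] - 1) * w)) / sum(w)
    cen <- cen * spacing                          # (x, y, z) um
    objs[[length(objs) + 1L]] <- list(voxels = vx, centroid = cen)
  }
  if (length(objs)) {
    key <- t(vapply(objs, function(o) c(o$centroid[3], o$centroid[2], o$centroid[1]),
                    numeric(3)))
    ord <- order(key[, 1], key[, 2], key[, 3])
    objs <- objs[ord]
  }
  lab_out <- array(0L, dims)
  res <- vector("list", length(objs))
  for (i in seq_along(objs)) {
    res[[i]] <- new_segmented_object(i, objs[[i]]$voxels, objs[[i]]$centroid,
                                     channel, th)
    lab_out[objs[[i]]$voxels] <- i
  }
  attr(res, "label_map") <- lab_out
  attr(res, "log") <- list(threshold = th, n_raw = ncomp, n_filtered = n_filt)
  attr(res, "spacing") <- spacing
  res
}

new_iso_mesh <- function(vertices, faces) {
  closed <- FALSE
  if (nrow(faces) > 0) {
    e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    closed <- all(table(key) == 2L)
  }
  structure(list(vertices = vertices, faces = faces, closed = closed),
            class = "iso_mesh")
}

#' @export
print.iso_mesh <- function(x, ...) {
  cat(sprintf("<iso_mesh> %d vertices, %d triangles, %s\n",
              nrow(x$vertices), nrow(x$faces),
              if (x$closed) "closed" else "open"))
  invisible(x)
}

#' Euler characteristic of a triangle mesh (V - E + F)
#' @param mesh An `iso_mesh`.
#' @return Integer: 2 for a topological sphere, 0 for a torus.
#' @export
euler_characteristic <- function(mesh) {
  e <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)], mesh$faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  nrow(mesh$vertices) - length(unique(key)) + nrow(mesh$faces)
}

#' Extract the isosurface mesh of a segmented object
#'
#' Marching-tetrahedra triangulation of the level set at `iso_level` within
#' the object's padded bounding box, in physical um coordinates (anisotropic
#' voxel spacing respected). Voxels belonging to other labelled objects are
#' zeroed first so touching neighbours do not leak into the surface.
#'
#' @param object A `segmented_object` from [segment_granules()].
#' @param grid The [voxel_grid()] (or array) the object was segmented from.
#' @param iso_level Iso value; defaults to the segmentation threshold.
#' @param label_map Optional label array (taken from the segmentation result
#'   attribute) for masking neighbours.
#' @param smooth_voxels Gaussian pre-smoothing sigma in voxels applied to the
#'   cropped field before triangulation (default 0.6). Regularizes the level
#'   set so the triangulated area converges to the true surface area instead
#'   of the jagged voxel surface; set 0 to disable.
#' @param spacing Required for array input.
#' @return An `iso_mesh` with `vertices` (um, columns x,y,z), `faces`
#'   (1-based triangles) and a `closed` flag.
#' @export
extract_isosurface_mesh <- function(object, grid, iso_level = NULL,
                                    label_map = NULL, smooth_voxels = 0.6,
                                    spacing = NULL) {
  stopifnot(inherits(object, "segmented_object"))
  if (inherits(grid, "voxel_grid")) {
    vol <- get_channel(grid, object$channel)
    spacing <- grid$spacing
  } else {
    vol <- grid
    if (is.null(spacing)) stop("`spacing` required for array input")
  }
  if (is.null(iso_level)) iso_level <- object$threshold
  if (object$n_voxels < 1) stop("object is empty")
  vx <- object$voxels
  span <- apply(vx, 2, max) - apply(vx, 2, min) + 1L
  if (any(span < 2L))
    stop("object is thinner than one voxel along an axis; mesh would be degenerate")
  dims <- dim(vol)
  pad <- 2L + as.integer(ceiling(3 * smooth_voxels))
  lo <- pmax(apply(vx, 2, min) - pad, 1L)
  hi <- pmin(apply(vx, 2, max) + pad, dims)
  crop <- vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  if (!is.null(label_map)) {
    lcrop <- label_map[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    crop[lcrop != 0L & lcrop != object$label] <- 0
  }
  if (smooth_voxels > 0) crop <- gaussian_smooth_voxels(crop, smooth_voxels)
  # zero border so the level set closes even if the object touches the crop edge
  crop[c(1, dim(crop)[1]), , ] <- 0
  crop[, c(1, dim(crop)[2]), ] <- 0
  crop[, , c(1, dim(crop)[3])] <- 0
  mm <- marching_tetrahedra(as.vector(crop), dim(crop), spacing_zyx(spacing), iso_level)
  verts <- mm$vertices
  if (nrow(verts)) {
    verts[, 1] <- verts[, 1] + (lo[3] - 1) * spacing[1]
    verts[, 2] <- verts[, 2] + (lo[2] - 1) * spacing[2]
    verts[, 3] <- verts[, 3] + (lo[1] - 1) * spacing[3]
  }
  colnames(verts) <- c("x", "y", "z")
  new_iso_mesh(verts, mm$faces)
}

#' Segment the nucleus channel
#'
#' Thresholds the nucleus channel, keeps the largest 26-connected component
#' (logging any discarded blobs), fills interior holes by flood-filling the
#' background from the volume border, and triangulates the closed nuclear
#' isosurface used as the reference for granule distances.
#'
#' @param grid A [voxel_grid()] or 3D array (then `spacing` required).
#' @param channel Channel name/index (default `"nucleus"` if present).
#' @param threshold Threshold spec (default Otsu).
#' @param spacing `c(dx, dy, dz)` um for array input.
#' @return A `nucleus_model`: `mask` (logical array), `mesh` (closed
#'   `iso_mesh`), `centroid` (`(x, y, z)` um), `spacing`, `n_discarded`.
#' @export
segment_nucleus <- function(grid, channel = NULL, threshold = "otsu",
                            spacing = NULL) {
  if (inherits(grid, "voxel_grid")) {
    if (is.null(channel))
      channel <- if ("nucleus" %in% names(grid$data)) "nucleus" else 1L
    vol <- get_channel(grid, channel)
    spacing <- grid$spacing
  } else {
    vol <- grid
    if (is.null(spacing)) stop("`spacing` required for array input")
  }
  if (max(vol) <= 0) stop("no nucleus detected: channel is empty")
  th <- resolve_threshold(vol, threshold)
  mask <- vol > th
  if (!any(mask)) stop("no nucleus detected above threshold")
  dims <- dim(vol)
  lab <- cc_label_3d(as.vector(mask), dims, 26L)
  ncomp <- attr(lab, "n_components")
  if (ncomp > 1) {
    sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
    keep <- which.max(sizes)
    message(ncomp - 1L, " smaller component(s) discarded while segmenting the nucleus")
    mask <- array(lab == keep, dims)
  }
  # fill holes: background voxels 6-connected to the border stay background
  bg <- cc_label_3d(as.vector(!mask), dims, 6L)
  bg <- array(bg, dims)
  border_labels <- unique(c(bg[c(1, dims[1]), , ], bg[, c(1, dims[2]), ], bg[, , c(1, dims[3])]))
  border_labels <- border_labels[border_labels > 0L]
  filled <- mask | (bg > 0L & !(bg %in% border_labels))
  idx <- which(filled, arr.ind = TRUE)
  cen <- c(mean(idx[, 3] - 1) * spacing[1], mean(idx[, 2] - 1) * spacing[2],
           mean(idx[, 1] - 1) * spacing[3])
  fvol <- array(0, dims)
  fvol[filled] <- 1
  fvol[c(1, dims[1]), , ] <- 0
  fvol[, c(1, dims[2]), ] <- 0
  fvol[, , c(1, dims[3])] <- 0
  mm <- marching_tetrahedra(as.vector(fvol), dims, spacing_zyx(spacing), 0.5)
  verts <- mm$vertices
  colnames(verts) <- c("x", "y", "z")
  structure(list(mask = filled, mesh = new_iso_mesh(verts, mm$faces),
                 centroid = cen, spacing = spacing,
                 n_discarded = max(ncomp - 1L, 0L)),
            class = "nucleus_model")
}
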