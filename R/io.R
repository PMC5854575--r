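#' Write a voxel grid as a multi-page TIFF with a JSON metadata sidecar
#'
#' Slices are written as 32-bit pages ordered z-within-channel. TIFF samples
#' are fixed-point values on a dyadic grid, so intensities are divided by a
#' power-of-two scale chosen from the data maximum (power-of-two scaling is
#' exact in floating point) and quantized to the file's 32-bit grid: the
#' round trip is bit-exact for any data already on that grid — in particular
#' every integer-valued (photon-count) image below 2^31 and anything
#' previously written by this function — and otherwise quantizes with
#' relative error below 2^-31. Voxel spacing, channel names, array shape and
#' the intensity scale are stored in `<path>.json` alongside the image.
#'
#' @param grid A [voxel_grid()].
#' @param path Output TIFF path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  mx <- max(vapply(grid$data, max, numeric(1)), 0)
  k <- if (mx > 0) floor(log2(mx)) + 1 else 0
  # fixed-point encoding: sample integer n = round(x * 2^(31-k)) < 2^31.
  # The TIFF library stores floor(y * (2^32-1)) and reads back n / 2^32, so
  # the written value carries a half-integer offset to land exactly on n.
  step <- 2^(31 - k)
  scale <- 2^(k + 1)            # read-back multiplier: x = n / step
  pages <- list()
  for (ch in names(grid$data)) {
    arr <- (round(grid$data[[ch]] * step) + 0.5) / (2^32 - 1)
    for (i in seq_len(grid$dim[1])) pages[[length(pages) + 1L]] <- arr[i, , ]
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- list(
    spacing_um = unname(grid$spacing),           # (dx, dy, dz)
    channels = names(grid$data),
    shape_zyx = unname(grid$dim),
    intensity_scale = scale
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF into a voxel grid
#'
#' Metadata (voxel spacing, channel layout, intensity scale) is taken from
#' the `<path>.json` sidecar written by [write_volume()]. For TIFFs from
#' other sources, with no sidecar, `spacing` must be supplied explicitly —
#' a missing voxel size is an error, never a silent default.
#'
#' @param path TIFF path.
#' @param spacing Optional `c(dx, dy, dz)` um override; required when no
#'   sidecar exists.
#' @param channels Optional channel names; with `n` names the pages are
#'   split into `n` equal z-stacks (z-within-channel order).
#' @return A [voxel_grid()].
#' @export
read_volume <- function(path, spacing = NULL, channels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else NULL
  if (is.null(spacing)) {
    if (is.null(meta) || is.null(meta$spacing_um))
      stop("voxel spacing not found in metadata and no `spacing` override supplied")
    spacing <- as.numeric(meta$spacing_um)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  if (is.null(channels)) channels <- if (!is.null(meta)) meta$channels else "ch1"
  nch <- length(channels)
  if (length(pages) %% nch != 0)
    stop("page count ", length(pages), " not divisible by ", nch, " channels")
  nz <- length(pages) %/% nch
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  data <- list()
  for (c_i in seq_len(nch)) {
    arr <- array(0, c(nz, ny, nx))
    for (i in seq_len(nz)) arr[i, , ] <- pages[[(c_i - 1) * nz + i]]
    data[[channels[c_i]]] <- arr * scale
  }
  voxel_grid(data, spacing = spacing)
}
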