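#' Volumetric image container
#'
#' A `voxel_grid` holds one or more co-registered 3D intensity channels with
#' physical voxel spacing. Arrays are stored in `(z, y, x)` order with the
#' first index fastest; `z = 1` is the bottom of the sample (basal side of an
#' epidermis stack). Physical coordinates are 0-based voxel index times
#' spacing, so voxel `(1, 1, 1)` sits at the origin and a voxel's coordinate
#' is its centre.
#'
#' @param data A 3D numeric array in `(z, y, x)` order, or a named list of
#'   such arrays (one per channel, equal dimensions).
#' @param spacing Numeric length-3 voxel spacing `c(dx, dy, dz)` in
#'   micrometres.
#' @param channels Optional channel names; defaults to names of `data` or
#'   `"ch1"`, `"ch2"`, ...
#' @return An object of class `voxel_grid`: a list with elements `data`
#'   (named list of arrays), `spacing` (named `c(x, y, z)`), `dim`
#'   (`c(nz, ny, nx)`).
#' @examples
#' g <- voxel_grid(array(0, c(8, 16, 16)), spacing = c(0.1, 0.1, 0.3))
#' dim(g)
#' @export
voxel_grid <- function(data, spacing, channels = NULL) {
  if (is.array(data) && length(dim(data)) == 3L) data <- list(data)
  if (!is.list(data) || !length(data)) stop("`data` must be a 3D array or a list of 3D arrays")
  dims <- dim(data[[1]])
  if (length(dims) != 3L) stop("channel arrays must be 3D (z, y, x)")
  for (ch in data) {
    if (!identical(dim(ch), dims)) stop("all channels must share the same dimensions")
    if (anyNA(ch) || any(!is.finite(ch))) stop("intensities must be finite")
    if (any(ch < 0)) stop("intensities must be non-negative")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive values (dx, dy, dz) in um")
  if (is.null(channels)) {
    channels <- names(data)
    if (is.null(channels) || any(!nzchar(channels)))
      channels <- paste0("ch", seq_along(data))
  }
  if (length(channels) != length(data)) stop("one name per channel required")
  names(data) <- channels
  structure(
    list(data = data, spacing = setNames(spacing, c("x", "y", "z")), dim = dims),
    class = "voxel_grid"
  )
}

#' @export
dim.voxel_grid <- function(x) x$dim

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf(
    "<voxel_grid> %d x %d x %d voxels (z,y,x), spacing %.4g x %.4g x %.4g um (x,y,z)\n",
    x$dim[1], x$dim[2], x$dim[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  cat("channels:", paste(names(x$data), collapse = ", "), "\n")
  invisible(x)
}

#' Extract one channel of a voxel grid
#'
#' @param grid A [voxel_grid()].
#' @param channel Channel name or index; default the first channel.
#' @return The channel's 3D array in `(z, y, x)` order.
#' @export
get_channel <- function(grid, channel = 1L) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.character(channel) && !channel %in% names(grid$data))
    stop("no channel named '", channel, "'")
  grid$data[[channel]]
}

#' Voxel spacing in array-axis (z, y, x) order
#' @param grid A [voxel_grid()].
#' @return Numeric `c(dz, dy, dx)` in um.
#' @keywords internal
spacing_zyx <- function(grid) {
  s <- if (inherits(grid, "voxel_grid")) grid$spacing else as.numeric(grid)
  unname(s[c(3, 2, 1)])
}

# physical (x, y, z) um coordinates of 1-based voxel indices (i=z, j=y, k=x)
voxel_to_um <- function(ijk, spacing_xyz) {
  ijk <- matrix(ijk, ncol = 3)
  cbind(
    x = (ijk[, 3] - 1) * spacing_xyz[1],
    y = (ijk[, 2] - 1) * spacing_xyz[2],
    z = (ijk[, 1] - 1) * spacing_xyz[3]
  )
}
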