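#' Signed distance from granule centroids to the nucleus surface
#'
#' Distance is the Euclidean distance to the nearest nucleus surface voxel
#' (a mask voxel with a 6-neighbour in the background), computed with an
#' exact distance transform honouring anisotropic voxel spacing; the sign is
#' negative for centroids inside the nucleus mask. This reproduces the
#' inside/outside dichotomy of nucleus-relative granule positions and is
#' well defined for any nucleus shape.
#'
#' @param centroids Numeric `(x, y, z)` um vector or an n x 3 matrix.
#' @param nucleus A `nucleus_model` from [segment_nucleus()].
#' @return Signed distances in um (negative inside the nucleus).
#' @export
signed_distance_to_nucleus <- function(centroids, nucleus) {
  stopifnot(inherits(nucleus, "nucleus_model"))
  p <- matrix(centroids, ncol = 3)
  mask <- nucleus$mask
  dims <- dim(mask)
  spacing <- nucleus$spacing
  ijk <- cbind(round(p[, 3] / spacing[3]) + 1,
               round(p[, 2] / spacing[2]) + 1,
               round(p[, 1] / spacing[1]) + 1)
  if (any(ijk < 1) || any(ijk > matrix(dims, nrow(ijk), 3, byrow = TRUE)))
    stop("centroid outside image bounds")
  surf <- nucleus_surface_mask(mask)
  d <- edt_3d(as.vector(surf), dims, spacing_zyx(spacing))
  d <- array(d, dims)
  vals <- d[ijk]
  inside <- mask[ijk]
  ifelse(inside, -vals, vals)
}

# surface voxels: mask voxels with at least one 6-neighbour in the background
nucleus_surface_mask <- function(mask) {
  dims <- dim(mask)
  shift <- function(m, ax, by) {
    out <- array(FALSE, dims)
    idx_src <- lapply(dims, seq_len)
    idx_dst <- idx_src
    n <- dims[ax]
    if (by > 0) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    else        { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  has_bg <- array(FALSE, dims)
  for (ax in 1:3) for (by in c(-1, 1)) has_bg <- has_bg | !shift(mask, ax, by)
  # border mask voxels are surface by convention
  mask & has_bg
}

#' Normalize an axial position to the local epidermis height
#'
#' Granule z positions are expressed relative to the total height of the
#' epidermal sample, so 0 is the basal side and 1 the outermost layer.
#'
#' @param z Axial position(s) in um, in `[0, sample_height]`.
#' @param sample_height Total sample height in um (> 0).
#' @return `z / sample_height` in `[0, 1]`.
#' @export
normalized_height <- function(z, sample_height) {
  if (sample_height <= 0) stop("sample_height must be > 0")
  if (any(z < 0) || any(z > sample_height))
    stop("z must lie within [0, sample_height]")
  z / sample_height
}

#' Smoothing-spline trend fit with degree selected by cross-validation
#'
#' Regression splines of degree 1 to 3 with 0-4 interior knots are fitted by
#' least squares; the degree/knot combination is chosen by generalized
#' cross-validation, `GCV = n RSS / (n - p)^2`. Ties (e.g. several exact
#' fits) go to the smallest model.
#'
#' @param x Predictor values.
#' @param y Response values.
#' @param degrees Candidate spline degrees (subset of 1:3).
#' @param max_knots Maximum number of interior knots.
#' @return A `trend_fit`: `grid` (100 predictor points spanning the observed
#'   range), `fitted` (values on the grid), `degree`, `df`, `residual_rms`,
#'   `gcv`, and the underlying `lm` fit.
#' @export
fit_trend <- function(x, y, degrees = 1:3, max_knots = 4L) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (length(unique(x)) < 2) stop("need at least 2 distinct predictor values for a trend")
  best <- NULL
  for (d in degrees) {
    for (k in 0:max_knots) {
      p <- d + k + 1L
      if (p + 1L > n || p + 1L > length(unique(x))) next
      fit <- tryCatch(lm(y ~ splines::bs(x, degree = d, df = d + k)),
                      error = function(e) NULL)
      if (is.null(fit) || anyNA(coef(fit))) next
      rss <- sum(fit$residuals^2)
      gcv <- n * rss / (n - p)^2
      if (is.null(best) || gcv < best$gcv - 1e-12 ||
          (abs(gcv - best$gcv) <= 1e-12 && p < best$p)) {
        best <- list(fit = fit, gcv = gcv, p = p, degree = d, rss = rss)
      }
    }
  }
  if (is.null(best)) stop("no spline model could be fitted")
  grid <- seq(min(x), max(x), length.out = 100)
  structure(list(
    grid = grid,
    fitted = as.numeric(predict(best$fit, newdata = data.frame(x = grid))),
    degree = best$degree, df = best$p,
    residual_rms = sqrt(best$rss / n), gcv = best$gcv, lm = best$fit
  ), class = "trend_fit")
}

#' Per-group summaries, trend curves and group comparison
#'
#' Computes mean, SD and SDM (standard error of the mean, sd/sqrt(n)) of a
#' granule parameter per experimental group — e.g. per calcium concentration
#' — optionally split into single granules (length <= 3 um) and aggregates
#' (> 3 um), the red/blue populations of the scatter analyses. When the
#' grouping variable is numeric, a smoothing-spline trend ([fit_trend()]) is
#' fitted through the rows; `compare = c(g1, g2)` adds an unpaired
#' two-sample t-test between two groups.
#'
#' @param table Population table: granule records plus grouping columns.
#' @param parameter Column to summarise (e.g. `"volume_um3"`).
#' @param group_by Grouping column (e.g. `"calcium_mM"`).
#' @param size_split Split by `size_class` (requires that column).
#' @param compare Optional two group levels for an unpaired t-test.
#' @return List with `group_stats` (tibble: group, [size_class,] n, mean,
#'   sd, sdm), `trend` (a `trend_fit`, or a list of them when split;
#'   `NULL` when the predictor is not numeric or has < 2 levels), and
#'   `t_test` (htest or `NULL`).
#' @export
trend_and_group_stats <- function(table, parameter, group_by,
                                  size_split = FALSE, compare = NULL) {
  stopifnot(parameter %in% names(table), group_by %in% names(table))
  df <- as.data.frame(table)
  df <- df[is.finite(df[[parameter]]) & !is.na(df[[group_by]]), , drop = FALSE]
  if (size_split && !"size_class" %in% names(df))
    stop("size_split requires a size_class column")
  grp_cols <- c(group_by, if (size_split) "size_class")
  key <- interaction(df[grp_cols], drop = TRUE)
  stats <- do.call(rbind, lapply(split(df, key), function(g) {
    out <- g[1, grp_cols, drop = FALSE]
    v <- g[[parameter]]
    out$n <- length(v)
    out$mean <- mean(v)
    out$sd <- if (length(v) > 1) sd(v) else NA_real_
    out$sdm <- out$sd / sqrt(out$n)
    out
  }))
  rownames(stats) <- NULL
  stats <- tibble::as_tibble(stats[order(stats[[group_by]]), , drop = FALSE])
  trend <- NULL
  if (is.numeric(df[[group_by]]) && length(unique(df[[group_by]])) >= 2) {
    fit_safe <- function(d) if (nrow(d) >= 3 && length(unique(d[[group_by]])) >= 2)
      fit_trend(d[[group_by]], d[[parameter]]) else NULL
    trend <- if (size_split) lapply(split(df, df$size_class), fit_safe) else fit_safe(df)
  }
  ttest <- NULL
  if (!is.null(compare)) {
    stopifnot(length(compare) == 2)
    a <- df[[parameter]][df[[group_by]] == compare[1]]
    b <- df[[parameter]][df[[group_by]] == compare[2]]
    if (!length(a) || !length(b)) stop("empty comparison group")
    if (sd(c(a, b)) == 0 || (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b))) {
      ttest <- list(statistic = c(t = 0), p.value = 1, method = "degenerate: zero variance")
    } else {
      ttest <- t.test(a, b, var.equal = FALSE)
    }
  }
  list(group_stats = stats, trend = trend, t_test = ttest)
}

#' Pearson colocalization coefficient of two channels
#'
#' The standard Pearson correlation of the two intensities over the masked
#' voxels: ~0 means no colocalization, ~1 full colocalization. The
#' coefficient is invariant to affine intensity rescaling of either channel.
#' Zero variance in either channel makes the coefficient undefined; `NA` is
#' returned with a warning rather than 0.
#'
#' @param channel_a,channel_b 3D arrays or [voxel_grid()] channels of equal
#'   shape.
#' @param mask Optional logical array restricting the analysed voxels.
#' @return Correlation in `[-1, 1]`, or `NA` when undefined.
#' @export
pearson_colocalization <- function(channel_a, channel_b, mask = NULL) {
  if (inherits(channel_a, "voxel_grid")) channel_a <- channel_a$data[[1]]
  if (inherits(channel_b, "voxel_grid")) channel_b <- channel_b$data[[1]]
  if (!identical(dim(channel_a), dim(channel_b)))
    stop("channels must have identical dimensions")
  a <- as.vector(channel_a); b <- as.vector(channel_b)
  if (!is.null(mask)) {
    m <- as.vector(mask)
    a <- a[m]; b <- b[m]
  }
  if (length(a) < 2) {
    warning("fewer than 2 voxels in the mask; coefficient undefined")
    return(NA_real_)
  }
  if (sd(a) == 0 || sd(b) == 0) {
    warning("zero variance in a channel; Pearson coefficient undefined")
    return(NA_real_)
  }
  cor(a, b)
}
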