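# Two-dimensional PCA projection of descriptor space and Nadaraya-Watson
# smoothed energy landscapes over the projection.

#' Project descriptors onto the first two principal components
#'
#' Column-centered PCA via the eigen-decomposition of the empirical
#' covariance matrix (through [stats::prcomp()]); components are sorted by
#' descending eigenvalue and each is sign-fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param X m x d descriptor matrix, m >= 3.
#' @param n_components Number of components (2, kept for clarity).
#' @return Object of class `"projection_2d"`: `scores` (m x 2),
#'   `explained_variance_ratio` (length 2), `loadings` (d x 2), `center`
#'   (length d).
#' @export
pca_project <- function(X, n_components = 2L) {
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop_data("pca_project needs at least 3 rows")
  if (n_components != 2L) stop_data("only 2 components are supported")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(p$rotation))
  load <- p$rotation[, seq_len(k), drop = FALSE]
  scores <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  if (k < 2L) {  # degenerate d = 1 input
    load <- cbind(load, 0)
    scores <- cbind(scores, 0)
  }
  var_all <- p$sdev^2
  ratio <- var_all[1:2] / sum(var_all)
  ratio[is.na(ratio)] <- 0
  colnames(scores) <- colnames(load) <- c("PC1", "PC2")
  structure(list(scores = scores,
                 explained_variance_ratio = ratio,
                 loadings = load,
                 center = p$center),
            class = "projection_2d")
}

#' @export
print.projection_2d <- function(x, ...) {
  cat(sprintf("<projection_2d: %d points, explained variance %.1f%% + %.1f%%>\n",
              nrow(x$scores), 100 * x$explained_variance_ratio[1],
              100 * x$explained_variance_ratio[2]))
  invisible(x)
}

#' Nadaraya-Watson smoothed energy landscape
#'
#' Locally weighted energy averages on a regular grid over the 2D
#' projection: at grid point g the value is
#' `sum_i w_i v_i / sum_i w_i` with Gaussian weights
#' `w_i = exp(-((gx - x_i)^2/hx^2 + (gy - y_i)^2/hy^2) / 2)`.
#' Per-axis bandwidths come from the normal reference rule
#' `h = 1.06 * sd * m^(-1/5)` multiplied by `smoothing_factor`.  Grid cells
#' receiving no kernel weight are masked (`NA`), not errors.
#'
#' @param points m x 2 matrix of projected coordinates (m >= 2).
#' @param values Length-m energies, kJ/mol.
#' @param grid_size Grid resolution per axis (default 200).
#' @param bandwidth_rule Only `"normal_reference"` is implemented.
#' @param smoothing_factor Bandwidth multiplier (default 0.3).
#' @return Object of class `"smoothed_grid"`: `grid_x`, `grid_y` (axis
#'   vectors), `values` (grid_size x grid_size matrix, x varying along
#'   rows), `bandwidths`, `smoothing_factor`.
#' @export
smooth_landscape <- function(points, values, grid_size = 200L,
                             bandwidth_rule = "normal_reference",
                             smoothing_factor = 0.3) {
  points <- as.matrix(points)
  values <- as.numeric(values)
  m <- nrow(points)
  if (m < 2L) stop_data("smooth_landscape needs >= 2 points")
  if (ncol(points) != 2L) stop_data("points must be m x 2")
  if (length(values) != m) stop_data("values must match points")
  if (!all(is.finite(points)) || !all(is.finite(values)))
    stop_data("points and values must be finite")
  bandwidth_rule <- match.arg(bandwidth_rule, "normal_reference")
  if (smoothing_factor <= 0) stop_data("smoothing_factor must be positive")

  nrr <- function(v) {
    s <- stats::sd(v)
    if (s == 0) s <- max(diff(range(v)), .Machine$double.eps)
    1.06 * s * m^(-1 / 5)
  }
  hx <- nrr(points[, 1]) * smoothing_factor
  hy <- nrr(points[, 2]) * smoothing_factor

  pad <- function(r) r + c(-1, 1) * 0.05 * diff(r)
  rx <- pad(range(points[, 1]))
  ry <- pad(range(points[, 2]))
  gx <- seq(rx[1], rx[2], length.out = grid_size)
  gy <- seq(ry[1], ry[2], length.out = grid_size)

  # separable Gaussian weights: W[g, i] per axis
  wx <- exp(-0.5 * (outer(gx, points[, 1], "-") / hx)^2)
  wy <- exp(-0.5 * (outer(gy, points[, 2], "-") / hy)^2)
  num <- wx %*% (t(wy) * values)   # recycles values down the m rows
  den <- wx %*% t(wy)
  vals <- num / den
  vals[den < .Machine$double.xmin] <- NA_real_

  structure(list(grid_x = gx, grid_y = gy, values = vals,
                 bandwidths = c(hx = hx, hy = hy),
                 smoothing_factor = smoothing_factor),
            class = "smoothed_grid")
}

#' @export
print.smoothed_grid <- function(x, ...) {
  cat(sprintf("<smoothed_grid: %d x %d, bandwidths (%.3g, %.3g), %.0f%% masked>\n",
              length(x$grid_x), length(x$grid_y),
              x$bandwidths[1], x$bandwidths[2],
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Plot a smoothed energy landscape
#'
#' Blue (low) to red (high) relative energy; masked cells are transparent.
#'
#' @param x A [smooth_landscape()] result.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.smoothed_grid <- function(x, ...) {
  pal <- grDevices::colorRampPalette(c("blue", "cyan", "yellow", "red"))(64)
  graphics::image(x$grid_x, x$grid_y, x$values, col = pal,
                  xlab = "PC1", ylab = "PC2", useRaster = TRUE, ...)
  invisible(x)
}

#' Export a smoothed grid as a long-format data frame
#'
#' @param x A [smooth_landscape()] result.
#' @return Data frame with columns `x`, `y`, `value`.
#' @export
grid_as_data_frame <- function(x) {
  data.frame(x = rep(x$grid_x, times = length(x$grid_y)),
             y = rep(x$grid_y, each = length(x$grid_x)),
             value = as.vector(x$values))
}
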