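#' 2D Gaussian kernel density of a point pattern
#'
#' Sum of isotropic Gaussian kernels evaluated at pixel centers of a regular
#' raster covering the window. No edge renormalization is applied, so mass
#' near the boundary leaks outside the raster; away from the boundary the
#' grid integrates to the point count. The kernel scale follows the
#' convention that a "100 um^2 Gaussian kernel" is the kernel *variance*,
#' i.e. `sigma = 10` um.
#'
#' @param p a [point_pattern] with at least 1 point after restriction.
#' @param sigma Gaussian kernel standard deviation in micrometres
#'   (default 10, i.e. variance 100 um^2).
#' @param pixel_size raster pixel edge in micrometres (default 10).
#' @param label restrict to one color label (optional).
#' @return Object of class `density_grid`: list with `values`
#'   (nx x ny matrix of densities per um^2; rows follow `xc`), `xc`, `yc`
#'   (pixel-center coordinates), `pixel_size`, `sigma`, `window`, `n`,
#'   `label`.
#' @export
kernel_density <- function(p, sigma = 10, pixel_size = 10, label = NULL) {
  p <- restrict_pattern(p, label)
  if (p$n < 1L) stop("kernel density undefined: empty pattern")
  if (sigma <= 0) stop("sigma must be positive")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  w <- p$window
  nx <- max(1L, ceiling((w[2] - w[1]) / pixel_size - 1e-9))
  ny <- max(1L, ceiling((w[4] - w[3]) / pixel_size - 1e-9))
  xc <- w[1] + (seq_len(nx) - 0.5) * pixel_size
  yc <- w[3] + (seq_len(ny) - 0.5) * pixel_size
  # separable kernel: values = A %*% t(B) / (2 pi sigma^2)
  A <- exp(-outer(xc, p$x, "-")^2 / (2 * sigma^2))   # nx x n
  B <- exp(-outer(yc, p$y, "-")^2 / (2 * sigma^2))   # ny x n
  vals <- (A %*% t(B)) / (2 * pi * sigma^2)
  structure(list(values = vals, xc = xc, yc = yc, pixel_size = pixel_size,
                 sigma = sigma, window = w, n = p$n, label = label),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("density_grid: %d x %d pixels of %g um, sigma = %g um, n = %d\n",
              length(x$xc), length(x$yc), x$pixel_size, x$sigma, x$n))
  invisible(x)
}

#' Threshold a density grid into a cluster mask
#'
#' Cluster boundaries are defined by the pixels carrying the highest
#' `top_fraction` of kernel density: the threshold is the
#' `1 - top_fraction` quantile of all pixel values inside the window, and the
#' mask is `density >= threshold`.
#'
#' @param d a `density_grid`.
#' @param top_fraction fraction of highest-density pixels retained
#'   (default 0.10, the top 10%).
#' @return Object of class `cluster_mask`: list with `mask` (logical matrix
#'   aligned to the grid), `threshold`, `quantile`, plus raster geometry.
#' @export
cluster_mask <- function(d, top_fraction = 0.10) {
  if (!inherits(d, "density_grid")) stop("d must be a density_grid")
  if (top_fraction <= 0 || top_fraction >= 1) {
    stop("top_fraction must be in (0, 1)")
  }
  v <- d$values
  if (max(v) - min(v) <= 0) stop("threshold degenerate: constant density grid")
  thr <- stats::quantile(v, probs = 1 - top_fraction, names = FALSE)
  structure(list(mask = v >= thr, threshold = thr, quantile = 1 - top_fraction,
                 pixel_size = d$pixel_size, window = d$window,
                 xc = d$xc, yc = d$yc),
            class = "cluster_mask")
}

#' Percent overlap of two cluster masks
#'
#' Quantifies how much two thresholded kernel-density cluster regions (e.g.
#' the RFP+ and GFP+ channels of one section) share territory. Two
#' denominators are provided because "relative to the combined area" admits
#' both readings:
#' \describe{
#'   \item{`union`}{`100 * |A and B| / |A or B|` (Jaccard percentage; default).}
#'   \item{`symmetric`}{`100 * |A and B| / |A or B minus A and B|`, i.e.
#'     intersection relative to the combined *non-overlapping* area.}
#' }
#' Areas are pixel counts on the shared raster.
#'
#' @param a,b `cluster_mask` objects on identical raster geometry.
#' @param definition `"union"` or `"symmetric"`.
#' @return Overlap percentage (can exceed 100 under `"symmetric"`).
#' @export
overlap_percent <- function(a, b, definition = c("union", "symmetric")) {
  definition <- match.arg(definition)
  if (!inherits(a, "cluster_mask") || !inherits(b, "cluster_mask")) {
    stop("a and b must be cluster_mask objects")
  }
  if (!identical(dim(a$mask), dim(b$mask)) ||
      abs(a$pixel_size - b$pixel_size) > 1e-9 ||
      any(abs(a$window - b$window) > 1e-9)) {
    stop("masks do not share raster geometry")
  }
  inter <- sum(a$mask & b$mask)
  uni <- sum(a$mask | b$mask)
  if (uni == 0L) stop("both masks are empty")
  if (definition == "union") {
    100 * inter / uni
  } else {
    if (uni == inter) return(Inf)  # identical non-empty masks
    100 * inter / (uni - inter)
  }
}

#' Write a cluster mask as a plain 0/1 CSV raster
#'
#' @param m a `cluster_mask`.
#' @param path output CSV path (rows = y pixels, columns = x pixels).
#' @export
write_mask <- function(m, path) {
  utils::write.table(t(m$mask) * 1L, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
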