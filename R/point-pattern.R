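#' Planar point pattern of segmented cell centroids
#'
#' Container for labeled cell coordinates inside a rectangular observation
#' window, as exported from segmented microscopy images (one row per cell).
#' Coordinates are planar and in micrometres; the window area `|W|` defines
#' the intensity estimate `lambda = n / |W|` used by the Ripley statistics.
#'
#' @param x,y numeric coordinates in micrometres.
#' @param window numeric length-4 vector `c(xmin, xmax, ymin, ymax)` in
#'   micrometres. If `NULL`, the bounding box of the points is used.
#' @param labels optional per-point categorical color label (e.g. `"RFP"`,
#'   `"GFP"`); recycled if length 1.
#' @param animal_id optional provenance string(s); recycled if length 1.
#' @param parent_id optional integer ground-truth clone assignment (used by
#'   the clonal simulator).
#' @return An object of class `point_pattern`: a list with elements `x`, `y`,
#'   `window`, `labels`, `animal_id`, `parent_id`, `n`.
#' @examples
#' pp <- point_pattern(c(10, 50), c(10, 50), window = c(0, 100, 0, 100))
#' pp$n
#' @export
point_pattern <- function(x, y, window = NULL, labels = NULL,
                          animal_id = NULL, parent_id = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("x and y must have equal length")
  }
  if (length(x) && (any(!is.finite(x)) || any(!is.finite(y)))) {
    stop("coordinates must be finite")
  }
  if (is.null(window)) {
    if (!length(x)) stop("window is required for an empty pattern")
    window <- c(min(x), max(x), min(y), max(y))
  }
  window <- as.numeric(window)
  if (length(window) != 4) {
    stop("window must be c(xmin, xmax, ymin, ymax)")
  }
  if (window_area(window) <= 0) {
    stop("window must have positive area")
  }
  out_of_window <- which(x < window[1] | x > window[2] |
                           y < window[3] | y > window[4])
  if (length(out_of_window)) {
    stop(sprintf("point(s) outside the declared window at row(s): %s",
                 paste(utils::head(out_of_window, 5L), collapse = ", ")))
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) == 1L) labels <- rep(labels, length(x))
    if (length(labels) != length(x)) stop("labels length mismatch")
  }
  if (!is.null(animal_id)) {
    animal_id <- as.character(animal_id)
    if (length(animal_id) == 1L) animal_id <- rep(animal_id, length(x))
    if (length(animal_id) != length(x)) stop("animal_id length mismatch")
  }
  if (!is.null(parent_id) && length(parent_id) != length(x)) {
    stop("parent_id length mismatch")
  }
  structure(list(x = x, y = y, window = window, labels = labels,
                 animal_id = animal_id, parent_id = parent_id,
                 n = length(x)),
            class = "point_pattern")
}

window_area <- function(window) {
  (window[2] - window[1]) * (window[4] - window[3])
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point_pattern: %d points in [%g, %g] x [%g, %g] um\n",
              x$n, x$window[1], x$window[2], x$window[3], x$window[4]))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

# Subset a pattern to one color label (NULL = all points).
restrict_pattern <- function(p, label = NULL) {
  if (is.null(label)) return(p)
  if (is.null(p$labels)) stop("pattern has no labels to restrict by")
  keep <- which(p$labels == label)
  point_pattern(p$x[keep], p$y[keep], window = p$window,
                labels = p$labels[keep],
                animal_id = if (!is.null(p$animal_id)) p$animal_id[keep],
                parent_id = if (!is.null(p$parent_id)) p$parent_id[keep])
}

#' Read cell centroids from CSV
#'
#' Expects columns `x_um` and `y_um` (micrometres); optional `label`,
#' `animal_id` and `parent_id` columns are carried along. Rows with missing
#' coordinates are dropped with a message reporting the count.
#'
#' @param path CSV file path.
#' @param window observation window `c(xmin, xmax, ymin, ymax)`; if `NULL`
#'   the bounding box of the points is used (zero padding).
#' @return A [point_pattern].
#' @export
read_points <- function(path, window = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    if (is.null(window)) stop("empty file and no window given")
    return(point_pattern(numeric(0), numeric(0), window = window))
  }
  if (!all(c("x_um", "y_um") %in% names(df))) {
    stop("CSV must contain columns x_um and y_um")
  }
  xs <- suppressWarnings(as.numeric(df$x_um))
  ys <- suppressWarnings(as.numeric(df$y_um))
  bad_numeric <- (!is.na(df$x_um) & is.na(xs)) | (!is.na(df$y_um) & is.na(ys))
  if (any(bad_numeric)) {
    stop(sprintf("non-numeric coordinates at row(s): %s",
                 paste(utils::head(which(bad_numeric), 5L), collapse = ", ")))
  }
  drop <- is.na(xs) | is.na(ys)
  if (any(drop)) {
    message(sprintf("dropped %d row(s) with missing coordinates", sum(drop)))
    df <- df[!drop, , drop = FALSE]
    xs <- xs[!drop]
    ys <- ys[!drop]
  }
  point_pattern(xs, ys, window = window,
                labels = if ("label" %in% names(df)) df$label,
                animal_id = if ("animal_id" %in% names(df)) df$animal_id,
                parent_id = if ("parent_id" %in% names(df)) df$parent_id)
}

#' Write a point pattern to CSV
#'
#' Columns: `x_um`, `y_um`, and any of `label`, `parent_id`, `animal_id`
#' present in the pattern.
#'
#' @param p a [point_pattern].
#' @param path output CSV path.
#' @export
write_points <- function(p, path) {
  df <- data.frame(x_um = p$x, y_um = p$y)
  if (!is.null(p$labels)) df$label <- p$labels
  if (!is.null(p$parent_id)) df$parent_id <- p$parent_id
  if (!is.null(p$animal_id)) df$animal_id <- p$animal_id
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Nearest-neighbor distances
#'
#' Per-cell Euclidean distance to the closest other cell, computed within one
#' color label when `label` is given (matching per-channel analyses of
#' sparsely labeled cells). No edge correction is applied.
#'
#' @param p a [point_pattern].
#' @param label restrict to this color label before computing (optional).
#' @return Numeric vector of distances (micrometres), one per retained point.
#' @examples
#' pp <- point_pattern(c(0, 3, 7), c(0, 0, 0), window = c(0, 10, -1, 1))
#' nearest_neighbor_distances(pp)  # 3 3 4
#' @export
nearest_neighbor_distances <- function(p, label = NULL) {
  p <- restrict_pattern(p, label)
  if (p$n < 2L) stop("NND undefined: fewer than 2 points")
  dm <- as.matrix(stats::dist(cbind(p$x, p$y)))
  diag(dm) <- Inf
  apply(dm, 1L, min)
}

#' Fraction of cells with NND at or below a threshold
#'
#' The tiling-scale clustering statistic: the percentage of cells whose
#' nearest same-label neighbor lies within `threshold` micrometres
#' (inclusive). Homeostatic microglia tile at roughly 50 um spacing, which is
#' the default threshold.
#'
#' @inheritParams nearest_neighbor_distances
#' @param threshold distance threshold in micrometres (default 50).
#' @return Percentage in `[0, 100]`.
#' @export
fraction_within <- function(p, threshold = 50, label = NULL) {
  d <- nearest_neighbor_distances(p, label = label)
  100 * mean(d <= threshold)
}
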