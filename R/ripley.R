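#' Ripley's K-function for a planar point pattern
#'
#' Estimates the cumulative second-order statistic
#' `K(r) = (1/n) * sum_i N_i(r) / lambda`, where `N_i(r)` is the number of
#' further points within distance `r` of point `i` and `lambda = n/|W|` is
#' the global intensity. Under complete spatial randomness (CSR)
#' `K(r) = pi r^2`; values above that indicate clustering.
#'
#' Corrections:
#' \describe{
#'   \item{`none`}{the raw definition above, with every pair counted once in
#'     each direction. Biased low near the window boundary.}
#'   \item{`border`}{reduced-sample estimator: the outer sum runs only over
#'     points at least `r` from the boundary and is renormalized by their
#'     number.}
#'   \item{`translation`}{each ordered pair `(i, j)` is weighted by
#'     `|W| / |W intersect W_shifted|`, the reciprocal fraction of the window
#'     in which the pair could have been observed (default; unbiased on
#'     rectangles).}
#' }
#'
#' @param p a [point_pattern] with at least 2 points (after `label`
#'   restriction).
#' @param r radius grid in micrometres; strictly increasing, starting at or
#'   above 0, with `max(r)` at most half the shorter window side. Default:
#'   0 to a quarter of the shorter side in 5 um steps.
#' @param correction one of `"translation"`, `"border"`, `"none"`.
#' @param label restrict to one color label first (optional).
#' @return Object of class `kest`: list with `r`, `K`, `correction`,
#'   `lambda`, `n`, `window`.
#' @examples
#' pp <- point_pattern(c(4.5, 5.5, 4.5, 5.5), c(4.5, 4.5, 5.5, 5.5),
#'                     window = c(0, 10, 0, 10))
#' ripley_k(pp, r = c(1.2, 1.5), correction = "none")$K  # 50 75
#' @export
ripley_k <- function(p, r = NULL, correction = c("translation", "border", "none"),
                     label = NULL) {
  correction <- match.arg(correction)
  p <- restrict_pattern(p, label)
  if (p$n < 2L) stop("Ripley's K undefined: fewer than 2 points")
  w <- p$window
  a <- w[2] - w[1]
  b <- w[4] - w[3]
  short <- min(a, b)
  if (is.null(r)) r <- seq(0, short / 4, by = 5)
  r <- as.numeric(r)
  if (any(diff(r) <= 0) || r[1] < 0) {
    stop("r must be strictly increasing and non-negative")
  }
  if (max(r) > short / 2) {
    stop("max(r) must not exceed half the shorter window side")
  }
  n <- p$n
  area <- a * b
  lambda <- n / area

  if (correction == "border") {
    # distance of each point to the window boundary
    bdist <- pmin(p$x - w[1], w[2] - p$x, p$y - w[3], w[4] - p$y)
    dm <- as.matrix(stats::dist(cbind(p$x, p$y)))
    diag(dm) <- Inf
    K <- vapply(r, function(ri) {
      keep <- bdist >= ri
      m <- sum(keep)
      if (m == 0L) return(NA_real_)
      counts <- rowSums(dm[keep, , drop = FALSE] <= ri)
      mean(counts) / lambda
    }, numeric(1))
  } else {
    d <- stats::dist(cbind(p$x, p$y))      # unordered pairs
    if (correction == "translation") {
      dx <- stats::dist(p$x, method = "manhattan")
      dy <- stats::dist(p$y, method = "manhattan")
      wt <- area / ((a - dx) * (b - dy))   # symmetric pair weight
    } else {
      wt <- rep(1, length(d))
    }
    ord <- order(d)
    csum <- cumsum(wt[ord])
    idx <- findInterval(r, d[ord])         # pairs with d <= r
    total <- ifelse(idx == 0L, 0, csum[pmax(idx, 1L)])
    K <- 2 * total / (n * lambda)          # each unordered pair counted twice
  }
  structure(list(r = r, K = K, correction = correction, lambda = lambda,
                 n = n, window = w),
            class = "kest")
}

#' @export
print.kest <- function(x, ...) {
  cat(sprintf("Ripley K estimate (%s correction): n = %d, lambda = %.3g/um^2, r in [%g, %g]\n",
              x$correction, x$n, x$lambda, min(x$r), max(x$r)))
  invisible(x)
}

#' Variance-stabilizing H-transform of Ripley's K
#'
#' `H(r) = sqrt(K(r)/pi) - r`. Zero under CSR, positive under clustering,
#' negative under dispersion; preferred for visual comparison against the
#' CSR null line.
#'
#' @param k a `kest` object from [ripley_k()].
#' @return Object of class `hest`: list with `r`, `H`, `smoothed` (FALSE),
#'   `smoothing_half_width` (NA).
#' @export
k_to_h <- function(k) {
  if (!inherits(k, "kest")) stop("k must be a kest object")
  if (any(k$K < 0, na.rm = TRUE)) stop("negative K: invalid upstream estimate")
  structure(list(r = k$r, H = sqrt(k$K / pi) - k$r,
                 smoothed = FALSE, smoothing_half_width = NA_real_),
            class = "hest")
}

#' Moving-average smoothing of an H-function
#'
#' Replaces `H(r)` by the mean of H over grid radii in
#' `[r - half_width, r + half_width]`. The window shrinks (truncates) at the
#' grid edges rather than padding, so no data are invented there.
#'
#' @param h an `hest` object.
#' @param half_width half-width of the moving-average window in micrometres
#'   (default 15, i.e. the interval `[r - 15, r + 15]`).
#' @return A smoothed `hest` (the `smoothed` flag is set).
#' @export
smooth_h <- function(h, half_width = 15) {
  if (!inherits(h, "hest")) stop("h must be an hest object")
  if (half_width < 0) stop("half_width must be non-negative")
  r <- h$r
  if (length(r) > 1L) {
    steps <- diff(r)
    if (max(steps) - min(steps) > 1e-8 * max(steps)) {
      stop("smoothing requires a regular radius grid")
    }
  }
  eps <- 1e-9 * max(1, max(abs(r)))
  Hs <- vapply(seq_along(r), function(i) {
    mean(h$H[abs(r - r[i]) <= half_width + eps], na.rm = TRUE)
  }, numeric(1))
  structure(list(r = r, H = Hs, smoothed = TRUE,
                 smoothing_half_width = half_width),
            class = "hest")
}

#' Average H-functions across animals
#'
#' Per-radius mean and standard error (SEM) across a group of per-animal
#' H-function estimates sharing one radius grid, as used to summarize a
#' treatment group.
#'
#' @param estimates list of `hest` objects on identical radius grids.
#' @return `data.frame` with columns `r_um`, `mean_H`, `sem_H`.
#' @export
group_average_h <- function(estimates) {
  if (!length(estimates)) stop("no estimates supplied")
  if (!all(vapply(estimates, inherits, logical(1), "hest"))) {
    stop("all elements must be hest objects")
  }
  r <- estimates[[1L]]$r
  for (e in estimates) {
    if (length(e$r) != length(r) || any(abs(e$r - r) > 1e-9)) {
      stop("mismatched radius grids")
    }
  }
  mat <- do.call(rbind, lapply(estimates, `[[`, "H"))
  k <- nrow(mat)
  sem <- if (k == 1L) rep(0, ncol(mat)) else apply(mat, 2L, stats::sd) / sqrt(k)
  data.frame(r_um = r, mean_H = colMeans(mat), sem_H = sem)
}

#' Cluster domain size from the H-function maximum
#'
#' The radius at which the smoothed H-function attains its maximum is used
#' as an estimate of the cluster domain scale. Ties are broken toward the
#' smallest radius (the more conservative domain size).
#'
#' @param h a smoothed `hest` (apply [smooth_h()] first; enforced).
#' @return Domain radius in micrometres.
#' @export
domain_size <- function(h) {
  if (!inherits(h, "hest")) stop("h must be an hest object")
  if (!isTRUE(h$smoothed)) stop("domain size requires a smoothed H; call smooth_h() first")
  if (all(is.na(h$H))) stop("H is all NA")
  h$r[which.max(h$H)]
}
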