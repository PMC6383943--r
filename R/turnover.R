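#' One-phase exponential decay fit of pulse-chase cell densities
#'
#' Fits `y(t) = (Y0 - plateau) * exp(-k * t) + plateau` by nonlinear least
#' squares, the standard model for the decay of an EdU-labeled cell cohort
#' when no further proliferation occurs. The half-life is `ln(2)/k`.
#'
#' Initialization is deterministic: `plateau0 = min(y)` (or the fixed
#' value), `k0` from a log-linear regression of `log(y - plateau0 + eps)` on
#' `t`, with additional starts at `k0/10` and `10*k0`; the converged fit with
#' the smallest residual sum of squares wins.
#'
#' @param t time in days (animal-level observations, not group means).
#' @param y cell density (e.g. cells per mm^2); non-negative.
#' @param plateau `"free"` to fit the asymptote with a lower bound of 0, or
#'   a single non-negative number to fix it (e.g. `0`).
#' @return Object of class `decay_fit`: list with `y0`, `plateau`, `k`
#'   (1/day), `half_life` (days), `sse`, `n_obs`, `fitted`, `plateau_mode`.
#' @examples
#' t <- c(0, 25, 50, 100)
#' y <- 100 * exp(-log(2) * t / 50)
#' fit_decay(t, y, plateau = 0)$half_life  # 50
#' @export
fit_decay <- function(t, y, plateau = "free") {
  t <- as.numeric(t)
  y <- as.numeric(y)
  if (length(t) != length(y)) stop("t and y must have equal length")
  if (any(!is.finite(t)) || any(!is.finite(y))) stop("non-finite observations")
  if (any(y < 0)) stop("densities must be non-negative")
  free_plateau <- identical(plateau, "free")
  if (!free_plateau) {
    plateau <- as.numeric(plateau)
    if (length(plateau) != 1L || !is.finite(plateau) || plateau < 0) {
      stop("plateau must be \"free\" or a single non-negative number")
    }
  }
  n_t <- length(unique(t))
  if (free_plateau && n_t < 3L) stop("insufficient timepoints: free plateau needs >= 3 distinct timepoints")
  if (!free_plateau && n_t < 2L) stop("insufficient timepoints: fixed plateau needs >= 2 distinct timepoints")
  if (stats::sd(y) == 0) stop("no decay detected: constant densities")

  p0 <- if (free_plateau) min(y) else plateau
  eps <- max(max(y), 1) * 1e-6
  amp <- pmax(y - p0, 0) + eps
  k_log <- -unname(stats::coef(stats::lm(log(amp) ~ t))[2L])
  if (!is.finite(k_log) || k_log <= 0) k_log <- log(2) / max(diff(range(t)), 1)
  starts <- unique(pmax(c(k_log / 10, k_log, k_log * 10), 1e-6))

  df <- data.frame(t = t, y = y)
  best <- NULL
  for (k0 in starts) {
    fit <- tryCatch({
      if (free_plateau) {
        minpack.lm::nlsLM(y ~ (Y0 - pl) * exp(-k * t) + pl, data = df,
                          start = list(Y0 = max(y), pl = p0, k = k0),
                          lower = c(Y0 = 0, pl = 0, k = 1e-10),
                          control = minpack.lm::nls.lm.control(maxiter = 500))
      } else {
        minpack.lm::nlsLM(y ~ (Y0 - p0) * exp(-k * t) + p0, data = df,
                          start = list(Y0 = max(y), k = k0),
                          lower = c(Y0 = 0, k = 1e-10),
                          control = minpack.lm::nls.lm.control(maxiter = 500))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best)) {
    stop(sprintf("decay fit did not converge (n = %d, %d distinct timepoints)",
                 length(y), n_t))
  }
  cf <- stats::coef(best$fit)
  k <- unname(cf["k"])
  if (k <= 1e-8) stop("no decay detected: rate estimate at zero")
  structure(list(y0 = unname(cf["Y0"]),
                 plateau = if (free_plateau) unname(cf["pl"]) else p0,
                 k = k,
                 half_life = log(2) / k,
                 sse = best$sse,
                 n_obs = length(y),
                 fitted = stats::fitted(best$fit),
                 plateau_mode = if (free_plateau) "free" else "fixed"),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "one-phase decay fit (plateau %s): Y0 = %.4g, plateau = %.4g, k = %.4g /day, T1/2 = %.4g days, SSE = %.4g, n = %d\n",
    x$plateau_mode, x$y0, x$plateau, x$k, x$half_life, x$sse, x$n_obs))
  invisible(x)
}

#' Half-life from a first-order decay rate
#'
#' @param k decay rate per day; must be positive.
#' @return Half-life in days, `ln(2)/k`.
#' @export
half_life_from_rate <- function(k) {
  if (any(k <= 0)) stop("k must be positive")
  log(2) / k
}

#' Linear regression between two density series
#'
#' Ordinary least squares of `y` on `x`, used to relate the decay of one
#' cell population to another (e.g. EdU+Iba1+ cohort versus total microglia)
#' across paired animal-level observations.
#'
#' @param x,y paired numeric observations, `n >= 3`.
#' @return Object of class `regression_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `n_obs`.
#' @export
decay_correlation <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::sd(y) == 0) 0 else
    suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 n_obs = length(x)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("linear regression: y = %.4g + %.4g x, R^2 = %.4f, n = %d\n",
              x$intercept, x$slope, x$r_squared, x$n_obs))
  invisible(x)
}
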