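# Independent brute-force oracles used to validate the fast implementations.

# Literal O(n^2) evaluation of K(r) = (1/n) sum_i N_i(r) / lambda with
# lambda = n/|W| and N_i(r) the number of other points within r of point i.
k_oracle <- function(p, r) {
  n <- p$n
  area <- (p$window[2] - p$window[1]) * (p$window[4] - p$window[3])
  dm <- as.matrix(stats::dist(cbind(p$x, p$y)))
  diag(dm) <- Inf
  vapply(r, function(ri) sum(dm <= ri) * area / n^2, numeric(1))
}

# Brute-force per-point nearest-neighbor distance via the full pair loop.
nnd_oracle <- function(x, y) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (j == i) next
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# Weighted trimmed mean of M-values, written out step by step from the
# Robinson-Oshlack definition: reference chosen by upper-quartile closeness
# to the mean, double trim on M (30%) and A (5%), inverse-variance weights,
# geometric-mean rescale.
tmm_oracle <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  lib <- colSums(counts)
  uq <- vapply(seq_len(ncol(counts)),
               function(i) stats::quantile(counts[, i] / lib[i], 0.75,
                                           names = FALSE),
               numeric(1))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(i) {
    obs <- counts[, i]
    rfc <- counts[, ref]
    nO <- lib[i]
    nR <- lib[ref]
    M <- log2((obs / nO) / (rfc / nR))
    A <- (log2(obs / nO) + log2(rfc / nR)) / 2
    v <- (nO - obs) / (nO * obs) + (nR - rfc) / (nR * rfc)
    fin <- is.finite(M) & is.finite(A) & (A > -1e10)
    M <- M[fin]; A <- A[fin]; v <- v[fin]
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * sum_trim) + 1
    hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Mean per-class recall (balanced accuracy over the label set of `truth`).
balanced_accuracy <- function(truth, predicted) {
  classes <- unique(truth)
  mean(vapply(classes, function(cl) {
    mean(predicted[truth == cl] == cl)
  }, numeric(1)))
}

# Build a cluster_mask object directly from a logical matrix (unit pixels),
# for hand-computable overlap fixtures.
mask_from_matrix <- function(m, pixel_size = 1) {
  structure(list(mask = m, threshold = NA_real_, quantile = NA_real_,
                 pixel_size = pixel_size,
                 window = c(0, nrow(m) * pixel_size, 0, ncol(m) * pixel_size),
                 xc = (seq_len(nrow(m)) - 0.5) * pixel_size,
                 yc = (seq_len(ncol(m)) - 0.5) * pixel_size),
            class = "cluster_mask")
}
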