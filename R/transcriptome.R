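#' Count dataset container
#'
#' Genes x samples non-negative integer counts plus a sample table mapping
#' each sample to its treatment group (e.g. Ctrl, 4D, 14D, 1Mo, P4).
#'
#' @param counts numeric matrix of non-negative counts with gene rownames
#'   and sample colnames.
#' @param samples `data.frame` with columns `sample_id` and `group`, or a
#'   character vector of groups in column order.
#' @return Object of class `count_dataset`.
#' @export
count_dataset <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("gene_%05d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("sample_%d", seq_len(ncol(counts)))
  }
  if (!is.data.frame(samples)) {
    samples <- data.frame(sample_id = colnames(counts),
                          group = as.character(samples))
  }
  if (!all(c("sample_id", "group") %in% names(samples))) {
    stop("samples must have columns sample_id and group")
  }
  missing <- setdiff(colnames(counts), samples$sample_id)
  if (length(missing)) {
    stop(sprintf("samples without a group: %s",
                 paste(utils::head(missing, 5L), collapse = ", ")))
  }
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  structure(list(counts = counts, samples = samples), class = "count_dataset")
}

#' @export
print.count_dataset <- function(x, ...) {
  tab <- table(x$samples$group)
  cat(sprintf("count_dataset: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Read a count dataset from TSV + sample-table CSV
#'
#' @param counts_path TSV of genes x samples; first column `gene`.
#' @param samples_path CSV with columns `sample_id`, `group`.
#' @return A [count_dataset].
#' @export
read_counts <- function(counts_path, samples_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1L]]
  count_dataset(counts, utils::read.csv(samples_path,
                                        stringsAsFactors = FALSE))
}

cpm_matrix <- function(counts, lib = colSums(counts)) {
  sweep(counts, 2L, lib / 1e6, "/")
}

#' Filter lowly expressed genes by CPM
#'
#' Retains genes with at least `min_cpm` counts per million in at least
#' `min_samples` samples, CPM computed on the raw library sizes. The
#' `literal` flag instead removes genes showing less than `min_cpm` CPM in
#' at least `min_samples` samples — a stricter reading that discards genes
#' silent in any `min_samples` libraries.
#'
#' @param cd a [count_dataset].
#' @param min_cpm CPM cutoff (default 1).
#' @param min_samples sample-count cutoff (default 3).
#' @param literal use the removal-rule reading (default FALSE).
#' @return Filtered [count_dataset].
#' @export
cpm_filter <- function(cd, min_cpm = 1, min_samples = 3, literal = FALSE) {
  stopifnot(inherits(cd, "count_dataset"))
  if (any(colSums(cd$counts) == 0)) stop("degenerate library: all-zero sample")
  cpm <- cpm_matrix(cd$counts)
  keep <- if (literal) {
    rowSums(cpm < min_cpm) < min_samples
  } else {
    rowSums(cpm >= min_cpm) >= min_samples
  }
  if (!any(keep)) stop("all genes removed by the CPM filter")
  count_dataset(cd$counts[keep, , drop = FALSE], cd$samples)
}

#' TMM normalization factors
#'
#' Weighted trimmed mean of M-values composition-bias factors
#' (Robinson-Oshlack), computed with edgeR and rescaled so their geometric
#' mean is 1. Multiply raw library sizes by these factors to obtain
#' effective library sizes.
#'
#' @param cd a [count_dataset] (already CPM-filtered).
#' @param logratio_trim,sum_trim trim fractions for M- and A-values
#'   (defaults 0.3 and 0.05).
#' @return Named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(cd, logratio_trim = 0.3, sum_trim = 0.05) {
  stopifnot(inherits(cd, "count_dataset"))
  if (any(colSums(cd$counts) == 0)) stop("degenerate library: all-zero sample")
  f <- edgeR::calcNormFactors(cd$counts, method = "TMM",
                              logratioTrim = logratio_trim,
                              sumTrim = sum_trim)
  stats::setNames(as.numeric(f), colnames(cd$counts))
}

log_cpm <- function(cd, norm_factors = NULL, prior = 0.5) {
  lib <- colSums(cd$counts)
  if (!is.null(norm_factors)) lib <- lib * norm_factors[colnames(cd$counts)]
  log2(cpm_matrix(cd$counts, lib) + prior)
}

#' Per-timepoint differential expression versus control
#'
#' Welch's unequal-variance t-test on log2(normalized CPM + 0.5), gene by
#' gene, between one timepoint group and the reference group, with
#' Benjamini-Hochberg FDR within the contrast. A gene is flagged DE when
#' `|log2FC| >= lfc_threshold` and `FDR < fdr_threshold` (the 2-fold /
#' FDR 0.05 rule by default). This is a deliberately simple, documented DE
#' engine; externally computed DE tables in the same schema can be fed
#' straight into [classify_return_kinetics()].
#'
#' @param cd a [count_dataset] (filtered).
#' @param group timepoint group to contrast.
#' @param ref reference group (default `"Ctrl"`).
#' @param norm_factors optional TMM factors from [tmm_factors()].
#' @param lfc_threshold absolute log2 fold-change cutoff (default 1).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return `data.frame` with columns `gene`, `contrast`, `log2fc`, `p`,
#'   `fdr`, `de`.
#' @export
de_test <- function(cd, group, ref = "Ctrl", norm_factors = NULL,
                    lfc_threshold = 1, fdr_threshold = 0.05) {
  stopifnot(inherits(cd, "count_dataset"))
  ga <- cd$samples$sample_id[cd$samples$group == group]
  gb <- cd$samples$sample_id[cd$samples$group == ref]
  if (length(ga) < 2L || length(gb) < 2L) {
    stop(sprintf("need >= 2 samples per group (%s: %d, %s: %d)",
                 group, length(ga), ref, length(gb)))
  }
  L <- log_cpm(cd, norm_factors)
  A <- L[, ga, drop = FALSE]
  B <- L[, gb, drop = FALSE]
  na <- ncol(A)
  nb <- ncol(B)
  ma <- rowMeans(A)
  mb <- rowMeans(B)
  va <- apply(A, 1L, stats::var)
  vb <- apply(B, 1L, stats::var)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df_w <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df_w)
  # zero variance in both groups: equal means are a clean null
  p[se2 == 0 & ma == mb] <- 1
  p[se2 == 0 & ma != mb] <- 0
  fdr <- stats::p.adjust(p, method = "BH")
  lfc <- ma - mb
  data.frame(gene = rownames(cd$counts),
             contrast = paste0(group, "_vs_", ref),
             log2fc = lfc, p = p, fdr = fdr,
             de = abs(lfc) >= lfc_threshold & fdr < fdr_threshold,
             row.names = NULL)
}

#' Classify genes by the kinetics of their homeostatic return
#'
#' Assigns each gene to a return-kinetics class from its DE status at the
#' three repopulation timepoints (all versus control):
#' fast = DE at 4D only; medium = DE at 4D and 14D but not 1Mo;
#' slow = DE at all three; delayed = DE at 14D only; every other flag
#' combination is `"none"`. The classes partition the gene universe.
#'
#' @param de4,de14,de1mo DE tables over the same gene universe (output of
#'   [de_test()] or an external table with columns `gene`, `log2fc`, `de`).
#' @return `data.frame` with columns `gene`, `class`, `dir_4d`, `dir_14d`,
#'   `dir_1mo` (sign of log2FC where DE, 0 otherwise).
#' @export
classify_return_kinetics <- function(de4, de14, de1mo) {
  for (d in list(de4, de14, de1mo)) {
    if (!all(c("gene", "log2fc", "de") %in% names(d))) {
      stop("DE tables need columns gene, log2fc, de")
    }
  }
  if (!identical(de4$gene, de14$gene) || !identical(de4$gene, de1mo$gene)) {
    stop("mismatched gene universes across DE tables")
  }
  f4 <- de4$de
  f14 <- de14$de
  f1 <- de1mo$de
  class <- rep("none", length(f4))
  class[f4 & !f14 & !f1] <- "fast"
  class[f4 & f14 & !f1] <- "medium"
  class[f4 & f14 & f1] <- "slow"
  class[!f4 & f14 & !f1] <- "delayed"
  data.frame(gene = de4$gene, class = class,
             dir_4d = ifelse(f4, sign(de4$log2fc), 0),
             dir_14d = ifelse(f14, sign(de14$log2fc), 0),
             dir_1mo = ifelse(f1, sign(de1mo$log2fc), 0),
             row.names = NULL)
}

#' Poisson-distance similarity between treatment groups
#'
#' Pairwise sample dissimilarities under a Poisson model: libraries are
#' first scaled to a common depth, then for each sample pair the root total
#' Poisson deviance from their per-gene average profile is taken. Group
#' distances are means over cross-replicate pairs; a group's self-distance
#' is 0 by definition. Similarity rescales distances to 0-100, with 100 on
#' the diagonal and 0 at the largest off-diagonal group distance.
#'
#' @param cd a [count_dataset] (filtered).
#' @return List with `sample_dist` (samples x samples), `group_dist` and
#'   `similarity` (groups x groups, ordered as first encountered).
#' @export
poisson_distance <- function(cd) {
  stopifnot(inherits(cd, "count_dataset"))
  counts <- cd$counts
  lib <- colSums(counts)
  if (any(lib == 0)) stop("degenerate library: all-zero sample")
  scaled <- sweep(counts, 2L, mean(lib) / lib, "*")
  ns <- ncol(scaled)
  D <- matrix(0, ns, ns, dimnames = list(colnames(counts), colnames(counts)))
  dev_term <- function(x, mu) {
    out <- numeric(length(x))
    pos <- x > 0
    out[pos] <- x[pos] * log(x[pos] / mu[pos])
    out
  }
  for (i in seq_len(ns - 1L)) {
    for (j in seq(i + 1L, ns)) {
      xi <- scaled[, i]
      xj <- scaled[, j]
      mu <- (xi + xj) / 2
      use <- mu > 0
      d2 <- 2 * sum(dev_term(xi[use], mu[use]) + dev_term(xj[use], mu[use]))
      D[i, j] <- D[j, i] <- sqrt(max(d2, 0))
    }
  }
  groups <- unique(cd$samples$group)
  singles <- names(which(table(cd$samples$group) == 1L))
  if (length(singles)) {
    warning(sprintf("group(s) with a single replicate: %s",
                    paste(singles, collapse = ", ")))
  }
  ng <- length(groups)
  G <- matrix(0, ng, ng, dimnames = list(groups, groups))
  for (i in seq_len(ng - 1L)) {
    for (j in seq(i + 1L, ng)) {
      si <- cd$samples$sample_id[cd$samples$group == groups[i]]
      sj <- cd$samples$sample_id[cd$samples$group == groups[j]]
      G[i, j] <- G[j, i] <- mean(D[si, sj])
    }
  }
  dmax <- max(G)
  S <- if (dmax > 0) 100 * (1 - G / dmax) else matrix(100, ng, ng,
                                                      dimnames = dimnames(G))
  diag(S) <- 100
  list(sample_dist = D, group_dist = G, similarity = S)
}

#' K-means clustering of relative expression profiles
#'
#' Clusters genes on the z-scored vector of group-mean log-CPM (relative
#' expression across the time course), with Lloyd-style k-means and
#' deterministic multi-restart given the seed.
#'
#' @param cd a [count_dataset] (filtered).
#' @param k number of clusters (default 4).
#' @param seed RNG seed for the restarts.
#' @param nstart random restarts (default 25); best within-cluster sum of
#'   squares wins.
#' @param norm_factors optional TMM factors.
#' @return List with `cluster` (named integer vector per gene), `centers`,
#'   `tot_withinss`, and `profile` (the standardized matrix clustered).
#' @export
kmeans_profiles <- function(cd, k = 4, seed = 1, nstart = 25,
                            norm_factors = NULL) {
  stopifnot(inherits(cd, "count_dataset"))
  if (k > nrow(cd$counts)) stop("k exceeds the number of genes")
  L <- log_cpm(cd, norm_factors)
  groups <- unique(cd$samples$group)
  M <- vapply(groups, function(g) {
    rowMeans(L[, cd$samples$sample_id[cd$samples$group == g], drop = FALSE])
  }, numeric(nrow(L)))
  mu <- rowMeans(M)
  sdv <- apply(M, 1L, stats::sd)
  Z <- (M - mu) / ifelse(sdv > 0, sdv, 1)  # flat genes stay at z = 0
  set.seed(seed)
  km <- stats::kmeans(Z, centers = k, nstart = nstart, iter.max = 100)
  list(cluster = stats::setNames(km$cluster, rownames(cd$counts)),
       centers = km$centers, tot_withinss = km$tot.withinss, profile = Z)
}
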