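#' Simulate complete spatial randomness (CSR)
#'
#' Homogeneous Poisson null model for the tiling analyses: `n` points drawn
#' uniformly and independently in a rectangular window. Used as the
#' reference against which clustering statistics (NND fractions, Ripley H)
#' are judged.
#'
#' @param n number of points.
#' @param window `c(xmin, xmax, ymin, ymax)` in micrometres; default a
#'   5000 x 5000 um square (25 mm^2, the scale of a hemibrain coronal
#'   section).
#' @param seed RNG seed; the draw is reproducible given the seed.
#' @param label optional color label assigned to every point.
#' @return A [point_pattern].
#' @export
sim_csr <- function(n, window = c(0, 5000, 0, 5000), seed = 1, label = NULL) {
  if (n < 0) stop("n must be non-negative")
  if (window_area(window) <= 0) stop("window must have positive area")
  set.seed(seed)
  x <- stats::runif(n, window[1], window[2])
  y <- stats::runif(n, window[3], window[4])
  point_pattern(x, y, window = window,
                labels = if (!is.null(label)) rep(label, n))
}

#' Simulate a clustered clonal point pattern (Thomas process)
#'
#' Emulates clonal expansion of sparsely labeled surviving cells: parents
#' are uniform in the window, each emits a Poisson number of offspring
#' displaced by an isotropic Gaussian, and every point of a clone carries
#' the color sampled once for its parent (or no label, with the remaining
#' probability). Offspring falling outside the window are clipped, matching
#' a tissue-section boundary. The ground-truth clone assignment is returned
#' in `parent_id`.
#'
#' @param n_parents number of surviving seed cells.
#' @param offspring_mean mean offspring per parent (Poisson).
#' @param dispersion_sigma isotropic Gaussian offspring displacement scale
#'   in micrometres; must be positive.
#' @param window observation rectangle (default 5000 x 5000 um).
#' @param label_probs named per-color labeling probabilities summing to at
#'   most 1 (default `c(RFP = 0.069, GFP = 0.099)`, sparse dual-color
#'   labeling); remaining mass is unlabeled.
#' @param seed RNG seed.
#' @param keep_unlabeled keep unlabeled clones in the pattern (default TRUE;
#'   unlabeled points carry label `"none"`).
#' @return A [point_pattern] with `labels` and `parent_id`.
#' @export
sim_thomas <- function(n_parents, offspring_mean, dispersion_sigma,
                       window = c(0, 5000, 0, 5000),
                       label_probs = c(RFP = 0.069, GFP = 0.099),
                       seed = 1, keep_unlabeled = TRUE) {
  if (n_parents < 0) stop("n_parents must be non-negative")
  if (offspring_mean < 0) stop("offspring_mean must be non-negative")
  if (dispersion_sigma <= 0) stop("dispersion_sigma must be positive")
  if (any(label_probs < 0) || any(label_probs > 1) || sum(label_probs) > 1) {
    stop("label_probs must be probabilities summing to at most 1")
  }
  if (window_area(window) <= 0) stop("window must have positive area")
  set.seed(seed)
  px <- stats::runif(n_parents, window[1], window[2])
  py <- stats::runif(n_parents, window[3], window[4])
  colors <- c(names(label_probs), "none")
  pcol <- if (n_parents > 0) {
    sample(colors, n_parents, replace = TRUE,
           prob = c(label_probs, 1 - sum(label_probs)))
  } else character(0)
  n_off <- stats::rpois(n_parents, offspring_mean)
  xs <- px
  ys <- py
  pid <- seq_len(n_parents)
  lab <- pcol
  if (n_parents > 0 && sum(n_off) > 0) {
    parent_of <- rep(seq_len(n_parents), n_off)
    ox <- px[parent_of] + stats::rnorm(sum(n_off), 0, dispersion_sigma)
    oy <- py[parent_of] + stats::rnorm(sum(n_off), 0, dispersion_sigma)
    xs <- c(xs, ox)
    ys <- c(ys, oy)
    pid <- c(pid, parent_of)
    lab <- c(lab, pcol[parent_of])
  }
  inside <- xs >= window[1] & xs <= window[2] &
    ys >= window[3] & ys <= window[4]
  keep <- inside & (keep_unlabeled | lab != "none")
  point_pattern(xs[keep], ys[keep], window = window, labels = lab[keep],
                parent_id = pid[keep])
}

#' Simulate an EdU pulse-chase density time course
#'
#' Per-animal densities following one-phase exponential decay,
#' `y(t) = (Y0 - plateau) * exp(-ln2 * t / half_life) + plateau`, with
#' additive Gaussian measurement noise. Defaults mirror a pulse-chase design
#' sampled at 14 days, 1, 2 and 4 months with the labeled-microglia
#' half-life of 111.3 days.
#'
#' @param timepoints days at which animals are sampled.
#' @param y0 initial density (cells/mm^2).
#' @param plateau asymptotic density; `y0 >= plateau >= 0`.
#' @param half_life half-life in days; positive.
#' @param noise_sd additive Gaussian noise SD (same units as density).
#' @param n_animals animals per timepoint.
#' @param population population label stored in the output.
#' @param seed RNG seed.
#' @return `data.frame` with columns `t_days`, `density_per_mm2`,
#'   `population`, `animal_id`, and attribute `truth` holding the generating
#'   parameters.
#' @export
sim_decay_series <- function(timepoints = c(14, 30, 60, 120), y0 = 100,
                             plateau = 0, half_life = 111.3, noise_sd = 5,
                             n_animals = 5, population = "EdU+Iba1+",
                             seed = 1) {
  if (half_life <= 0) stop("half_life must be positive")
  if (plateau < 0 || y0 < plateau) stop("need y0 >= plateau >= 0")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  set.seed(seed)
  t <- rep(timepoints, each = n_animals)
  mu <- (y0 - plateau) * exp(-log(2) * t / half_life) + plateau
  yv <- mu + stats::rnorm(length(t), 0, noise_sd)
  out <- data.frame(
    t_days = t,
    density_per_mm2 = yv,
    population = population,
    animal_id = paste0("animal_", rep(seq_len(n_animals), length(timepoints)),
                       "_t", t))
  attr(out, "truth") <- list(y0 = y0, plateau = plateau,
                             half_life = half_life, k = log(2) / half_life,
                             noise_sd = noise_sd)
  out
}

#' Simulate a count matrix with planted return-kinetics classes
#'
#' Negative-binomial RNA-seq counts for a repopulation time-course design
#' (control plus timepoint groups), with genes planted into kinetic
#' archetypes defined by which timepoints are shifted relative to control:
#' fast (4D only), medium (4D and 14D), slow (4D, 14D and 1Mo), delayed
#' (14D only), and null (no shift). Shift direction is random per gene with
#' magnitude `effect_log2fc`. Library sizes are drawn log-uniformly and
#' expected counts scale proportionally, so normalization is exercised.
#'
#' @param n_genes number of genes.
#' @param groups ordered group labels; must include `"Ctrl"`. A `"P4"` group,
#'   if present, receives the 4D-like shift (immature signature).
#' @param n_per_group samples per group.
#' @param archetype_fractions named proportions for
#'   `c(fast, medium, slow, delayed, null)`; must sum to 1.
#' @param effect_log2fc planted absolute log2 fold change at each shifted
#'   timepoint.
#' @param nb_dispersion negative-binomial dispersion (1/size); positive.
#' @param library_size_range range for log-uniform library sizes.
#' @param seed RNG seed.
#' @return List with `counts` (genes x samples integer matrix), `samples`
#'   (`data.frame` of `sample_id`, `group`), and `truth` (`data.frame` of
#'   `gene`, `class`, `sign`).
#' @export
sim_counts <- function(n_genes = 2000,
                       groups = c("Ctrl", "4D", "14D", "1Mo"),
                       n_per_group = 4,
                       archetype_fractions = c(fast = 0.08, medium = 0.05,
                                               slow = 0.04, delayed = 0.03,
                                               null = 0.80),
                       effect_log2fc = 3,
                       nb_dispersion = 0.05,
                       library_size_range = c(5e6, 2e7),
                       seed = 1) {
  if (!"Ctrl" %in% groups) stop("groups must include Ctrl")
  need <- c("fast", "medium", "slow", "delayed", "null")
  if (!all(need %in% names(archetype_fractions))) {
    stop("archetype_fractions must name fast, medium, slow, delayed, null")
  }
  archetype_fractions <- archetype_fractions[need]
  if (abs(sum(archetype_fractions) - 1) > 1e-8) {
    stop("archetype fractions must sum to 1")
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (any(library_size_range <= 0)) stop("library sizes must be positive")
  set.seed(seed)

  # deterministic class counts: largest-remainder apportionment
  exact <- archetype_fractions * n_genes
  cnt <- floor(exact)
  rem <- n_genes - sum(cnt)
  if (rem > 0) {
    add <- order(exact - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[add] <- cnt[add] + 1L
  }
  classes <- sample(rep(need, cnt))
  signs <- sample(c(-1, 1), n_genes, replace = TRUE)
  signs[classes == "null"] <- 0

  shifted_groups <- list(fast = "4D", medium = c("4D", "14D"),
                         slow = c("4D", "14D", "1Mo"), delayed = "14D",
                         null = character(0))
  if ("P4" %in% groups) {
    shifted_groups$fast <- c(shifted_groups$fast, "P4")
    shifted_groups$medium <- c(shifted_groups$medium, "P4")
    shifted_groups$slow <- c(shifted_groups$slow, "P4")
  }

  n_samples <- length(groups) * n_per_group
  sample_group <- rep(groups, each = n_per_group)
  sample_id <- paste0(sample_group, "_", rep(seq_len(n_per_group),
                                             length(groups)))
  lib <- exp(stats::runif(n_samples, log(library_size_range[1]),
                          log(library_size_range[2])))

  base <- stats::rlnorm(n_genes, meanlog = log(200), sdlog = 1.5)
  # per-gene per-group fold change
  fc <- matrix(1, n_genes, length(groups), dimnames = list(NULL, groups))
  for (cl in need) {
    g_idx <- which(classes == cl)
    for (gr in intersect(shifted_groups[[cl]], groups)) {
      fc[g_idx, gr] <- 2^(signs[g_idx] * effect_log2fc)
    }
  }
  rel <- base * fc[, sample_group, drop = FALSE]        # genes x samples
  # scale expected counts to the drawn library sizes
  mu <- sweep(rel, 2L, lib / colSums(rel), "*")
  counts <- matrix(
    stats::rnbinom(length(mu), mu = as.vector(mu), size = 1 / nb_dispersion),
    n_genes, n_samples)
  genes <- sprintf("gene_%05d", seq_len(n_genes))
  dimnames(counts) <- list(genes, sample_id)
  list(counts = counts,
       samples = data.frame(sample_id = sample_id, group = sample_group),
       truth = data.frame(gene = genes, class = classes, sign = signs))
}

#' Write a simulated count set to disk
#'
#' Counts as a TSV (genes x samples, first column `gene`) and the sample
#' table as CSV (`sample_id`, `group`).
#'
#' @param sim result of [sim_counts()].
#' @param counts_path output TSV path.
#' @param samples_path output CSV path.
#' @export
write_counts <- function(sim, counts_path, samples_path) {
  df <- data.frame(gene = rownames(sim$counts), sim$counts,
                   check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.csv(sim$samples, samples_path, row.names = FALSE)
  invisible(counts_path)
}
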