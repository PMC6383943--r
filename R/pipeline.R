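#' Run the spatial analysis track
#'
#' Chains centroid loading, NND tiling metrics, Ripley K/H with smoothing
#' and domain-size estimation, and dual-color kernel-density cluster
#' overlap, per animal and color channel, then summarizes per group.
#'
#' @param points a `data.frame` (or CSV path) with columns `x_um`, `y_um`,
#'   `label`, `animal_id`, and optionally `group`.
#' @param window observation window `c(xmin, xmax, ymin, ymax)`; if `NULL`,
#'   the per-animal bounding box is used.
#' @param out_dir output directory for CSV reports (created); `NULL` to
#'   skip writing.
#' @param labels color labels to analyze; default all labels present.
#' @param nnd_threshold tiling threshold in micrometres (default 50).
#' @param correction Ripley edge correction (default `"translation"`).
#' @param r_max,r_step radius grid; defaults to the [ripley_k()] grid.
#' @param smooth_half_width moving-average half-width (default 15 um).
#' @param kde_sigma,pixel_size,top_fraction kernel-density parameters.
#' @param overlap_definition `"union"` or `"symmetric"`.
#' @return Invisible list with `cells` (per animal x label summary),
#'   `h_curves`, `group_h` (if a `group` column is present), `overlap`.
#' @export
run_spatial <- function(points, window = NULL, out_dir = NULL, labels = NULL,
                        nnd_threshold = 50,
                        correction = "translation", r_max = NULL, r_step = 5,
                        smooth_half_width = 15, kde_sigma = 10,
                        pixel_size = 10, top_fraction = 0.10,
                        overlap_definition = "union") {
  if (is.character(points)) {
    if (!file.exists(points)) {
      stop(sprintf("input error: expected a centroid CSV at '%s'", points))
    }
    points <- utils::read.csv(points, stringsAsFactors = FALSE)
  }
  need <- c("x_um", "y_um", "label", "animal_id")
  if (!all(need %in% names(points))) {
    stop(sprintf("centroid table must have columns: %s",
                 paste(need, collapse = ", ")))
  }
  if (is.null(labels)) labels <- sort(unique(points$label))
  animals <- unique(points$animal_id)
  cell_rows <- list()
  h_rows <- list()
  overlap_rows <- list()
  h_by_group <- list()
  for (an in animals) {
    sub <- points[points$animal_id == an, , drop = FALSE]
    w <- if (is.null(window)) {
      c(min(sub$x_um), max(sub$x_um), min(sub$y_um), max(sub$y_um))
    } else window
    pp <- point_pattern(sub$x_um, sub$y_um, window = w, labels = sub$label,
                        animal_id = sub$animal_id)
    grp <- if ("group" %in% names(sub)) sub$group[1L] else NA_character_
    masks <- list()
    for (lb in labels) {
      sp <- restrict_pattern(pp, lb)
      if (sp$n < 2L) next
      d <- nearest_neighbor_distances(sp)
      r <- if (is.null(r_max)) NULL else seq(0, r_max, by = r_step)
      k <- tryCatch(ripley_k(sp, r = r, correction = correction),
                    error = function(e) {
                      stop(sprintf("stage ripley (animal %s, label %s): %s",
                                   an, lb, conditionMessage(e)))
                    })
      hs <- smooth_h(k_to_h(k), half_width = smooth_half_width)
      cell_rows[[length(cell_rows) + 1L]] <- data.frame(
        animal_id = an, group = grp, label = lb, n = sp$n,
        mean_nnd_um = mean(d),
        frac_within = 100 * mean(d <= nnd_threshold),
        domain_size_um = domain_size(hs))
      h_rows[[length(h_rows) + 1L]] <- data.frame(
        animal_id = an, group = grp, label = lb, r_um = hs$r, H_smoothed = hs$H)
      h_by_group[[paste(grp, lb, sep = "|")]] <-
        c(h_by_group[[paste(grp, lb, sep = "|")]], list(hs))
      masks[[lb]] <- cluster_mask(kernel_density(sp, sigma = kde_sigma,
                                                 pixel_size = pixel_size),
                                  top_fraction = top_fraction)
    }
    if (length(masks) >= 2L) {
      prs <- utils::combn(names(masks), 2L)
      for (cidx in seq_len(ncol(prs))) {
        la <- prs[1L, cidx]
        lb2 <- prs[2L, cidx]
        overlap_rows[[length(overlap_rows) + 1L]] <- data.frame(
          animal_id = an, group = grp, label_a = la, label_b = lb2,
          overlap_pct = overlap_percent(masks[[la]], masks[[lb2]],
                                        definition = overlap_definition))
      }
    }
  }
  if (!length(cell_rows)) stop("input error: no label with >= 2 points found")
  cells <- do.call(rbind, cell_rows)
  h_curves <- do.call(rbind, h_rows)
  overlap <- if (length(overlap_rows)) do.call(rbind, overlap_rows)
  group_h <- NULL
  if (any(!is.na(cells$group))) {
    group_h <- do.call(rbind, lapply(names(h_by_group), function(key) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
      avg <- group_average_h(h_by_group[[key]])
      data.frame(group = parts[1L], label = parts[2L], avg)
    }))
  }
  res <- list(cells = cells, h_curves = h_curves, group_h = group_h,
              overlap = overlap)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cells, file.path(out_dir, "spatial_cells.csv"),
                     row.names = FALSE)
    utils::write.csv(h_curves, file.path(out_dir, "h_curves.csv"),
                     row.names = FALSE)
    if (!is.null(group_h)) {
      utils::write.csv(group_h, file.path(out_dir, "group_h.csv"),
                       row.names = FALSE)
    }
    if (!is.null(overlap)) {
      utils::write.csv(overlap, file.path(out_dir, "overlap.csv"),
                       row.names = FALSE)
    }
    write_provenance(out_dir, "spatial",
                     list(nnd_threshold = nnd_threshold,
                          correction = correction,
                          smooth_half_width = smooth_half_width,
                          kde_sigma = kde_sigma, pixel_size = pixel_size,
                          top_fraction = top_fraction,
                          overlap_definition = overlap_definition))
  }
  invisible(res)
}

#' Run the turnover (pulse-chase decay) track
#'
#' Fits a one-phase exponential decay per population and, when both are
#' named, regresses the decay of one population on another across paired
#' animal-level observations (e.g. EdU-labeled microglia versus total
#' microglia).
#'
#' @param densities `data.frame` (or CSV path) with columns `t_days`,
#'   `density_per_mm2`, `population`, `animal_id`.
#' @param plateau `"free"` or a fixed non-negative value, passed to
#'   [fit_decay()].
#' @param correlate optional length-2 character vector
#'   `c(x_population, y_population)` for the decay correlation.
#' @param out_dir output directory for the fit table; `NULL` to skip.
#' @return Invisible list with `fits` (one row per population) and
#'   `correlation` (a `regression_fit` or `NULL`).
#' @export
run_turnover <- function(densities, plateau = "free", correlate = NULL,
                         out_dir = NULL) {
  if (is.character(densities)) {
    if (!file.exists(densities)) {
      stop(sprintf("input error: expected a density CSV at '%s'", densities))
    }
    densities <- utils::read.csv(densities, stringsAsFactors = FALSE)
  }
  need <- c("t_days", "density_per_mm2", "population", "animal_id")
  if (!all(need %in% names(densities))) {
    stop(sprintf("density table must have columns: %s",
                 paste(need, collapse = ", ")))
  }
  pops <- unique(densities$population)
  fits <- do.call(rbind, lapply(pops, function(pop) {
    sub <- densities[densities$population == pop, , drop = FALSE]
    fit <- fit_decay(sub$t_days, sub$density_per_mm2, plateau = plateau)
    data.frame(population = pop, y0 = fit$y0, plateau = fit$plateau,
               k_per_day = fit$k, half_life_days = fit$half_life,
               sse = fit$sse, n_obs = fit$n_obs)
  }))
  correlation <- NULL
  if (!is.null(correlate)) {
    if (!all(correlate %in% pops)) {
      stop(sprintf("missing population label(s): %s",
                   paste(setdiff(correlate, pops), collapse = ", ")))
    }
    a <- densities[densities$population == correlate[1L], , drop = FALSE]
    b <- densities[densities$population == correlate[2L], , drop = FALSE]
    key <- intersect(paste(a$animal_id, a$t_days),
                     paste(b$animal_id, b$t_days))
    xa <- a$density_per_mm2[match(key, paste(a$animal_id, a$t_days))]
    yb <- b$density_per_mm2[match(key, paste(b$animal_id, b$t_days))]
    correlation <- decay_correlation(xa, yb)
  }
  res <- list(fits = fits, correlation = correlation)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(fits, file.path(out_dir, "decay_fits.csv"),
                     row.names = FALSE)
    if (!is.null(correlation)) {
      utils::write.csv(data.frame(slope = correlation$slope,
                                  intercept = correlation$intercept,
                                  r_squared = correlation$r_squared,
                                  n_obs = correlation$n_obs),
                       file.path(out_dir, "decay_correlation.csv"),
                       row.names = FALSE)
    }
    write_provenance(out_dir, "turnover", list(plateau = plateau))
  }
  invisible(res)
}

#' Run the transcriptome kinetics track
#'
#' CPM filtering, TMM normalization, per-timepoint DE versus control,
#' return-kinetics classification, Poisson-distance group similarity, and
#' k-means expression clustering. A precomputed DE table (long format with
#' columns `gene`, `contrast`, `log2fc`, `p`, `fdr`, `de`) bypasses the
#' internal DE engine.
#'
#' @param cd a [count_dataset], or `counts_path` TSV (with `samples_path`
#'   CSV) via [read_counts()].
#' @param samples_path sample-table CSV when `cd` is a path.
#' @param timepoints timepoint groups contrasted against `ref`, in kinetic
#'   order 4D, 14D, 1Mo (defaults).
#' @param ref reference group (default `"Ctrl"`).
#' @param min_cpm,min_samples CPM filter parameters.
#' @param lfc_threshold,fdr_threshold DE rule parameters.
#' @param de_table optional precomputed long DE table.
#' @param k clusters for [kmeans_profiles()] (default 4).
#' @param seed seed for the k-means restarts.
#' @param out_dir output directory; `NULL` to skip writing.
#' @return Invisible list with `filtered_genes`, `tmm`, `de` (long table),
#'   `classes`, `class_counts`, `similarity`, `kmeans`.
#' @export
run_transcriptome <- function(cd, samples_path = NULL,
                              timepoints = c("4D", "14D", "1Mo"),
                              ref = "Ctrl", min_cpm = 1, min_samples = 3,
                              lfc_threshold = 1, fdr_threshold = 0.05,
                              de_table = NULL, k = 4, seed = 1,
                              out_dir = NULL) {
  if (is.character(cd)) cd <- read_counts(cd, samples_path)
  stopifnot(inherits(cd, "count_dataset"))
  filt <- cpm_filter(cd, min_cpm = min_cpm, min_samples = min_samples)
  nf <- tmm_factors(filt)
  if (is.null(de_table)) {
    des <- lapply(timepoints, function(g) {
      de_test(filt, g, ref = ref, norm_factors = nf,
              lfc_threshold = lfc_threshold, fdr_threshold = fdr_threshold)
    })
  } else {
    if (is.character(de_table)) {
      de_table <- utils::read.csv(de_table, stringsAsFactors = FALSE)
    }
    des <- lapply(timepoints, function(g) {
      sub <- de_table[de_table$contrast == paste0(g, "_vs_", ref), ,
                      drop = FALSE]
      if (!nrow(sub)) stop(sprintf("DE table lacks contrast %s_vs_%s", g, ref))
      sub[order(sub$gene), , drop = FALSE]
    })
  }
  names(des) <- timepoints
  classes <- classify_return_kinetics(des[[1L]], des[[2L]], des[[3L]])
  sim <- poisson_distance(filt)
  km <- kmeans_profiles(filt, k = k, seed = seed, norm_factors = nf)
  res <- list(filtered_genes = nrow(filt$counts), tmm = nf,
              de = do.call(rbind, des), classes = classes,
              class_counts = table(classes$class), similarity = sim,
              kmeans = km)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$de, file.path(out_dir, "de_table.csv"),
                     row.names = FALSE)
    utils::write.csv(classes, file.path(out_dir, "return_classes.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(sim$similarity),
                     file.path(out_dir, "group_similarity.csv"))
    utils::write.csv(data.frame(gene = names(km$cluster),
                                cluster = km$cluster),
                     file.path(out_dir, "kmeans_clusters.csv"),
                     row.names = FALSE)
    write_provenance(out_dir, "transcriptome",
                     list(min_cpm = min_cpm, min_samples = min_samples,
                          lfc_threshold = lfc_threshold,
                          fdr_threshold = fdr_threshold, k = k, seed = seed))
  }
  invisible(res)
}

#' Read a pipeline run configuration
#'
#' Plain YAML with one section per track (`spatial`, `turnover`,
#' `transcriptome`, `simulate`); values become the corresponding `run_*`
#' arguments.
#'
#' @param path YAML file path.
#' @return Named list of sections.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: '%s'", path))
  yaml::read_yaml(path)
}

# machine-readable provenance: parameters, package version, input hashes
write_provenance <- function(out_dir, stage, params, inputs = character(0)) {
  rec <- list(stage = stage,
              package_version = as.character(utils::packageVersion("microrepop")),
              parameters = params)
  if (length(inputs)) {
    rec$input_md5 <- as.list(tools::md5sum(inputs))
  }
  yaml::write_yaml(rec, file.path(out_dir, paste0(stage, "_provenance.yaml")))
  invisible(NULL)
}
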