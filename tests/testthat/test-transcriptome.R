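make_cd <- function(counts, groups) {
  count_dataset(counts, groups)
}

test_that("count_dataset validates counts and the sample table", {
  m <- matrix(1:12, 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  cd <- make_cd(m, c("Ctrl", "Ctrl", "4D", "4D"))
  expect_s3_class(cd, "count_dataset")
  expect_error(count_dataset(-m, c("a", "a", "b", "b")), "non-negative")
  expect_error(count_dataset(m, data.frame(sample_id = "s1", group = "a")),
               "without a group")
})

test_that("CPM filter keeps expressed genes under both rule readings", {
  lib <- 1e6
  m <- rbind(
    expressed = rep(10, 6),            # CPM 10 everywhere
    silent = rep(0, 6),                # removed
    split = c(2, 2, 2, 0.3, 0.3, 0.3)  # >=1 CPM in exactly 3 samples
  )
  m <- rbind(m, filler = lib - colSums(m))  # fix library size at 1e6
  colnames(m) <- paste0("s", 1:6)
  cd <- make_cd(m, rep(c("Ctrl", "4D"), each = 3))

  kept <- cpm_filter(cd, min_cpm = 1, min_samples = 3)
  expect_true(all(c("expressed", "split") %in% rownames(kept$counts)))
  expect_false("silent" %in% rownames(kept$counts))

  # literal removal rule: "split" shows < 1 CPM in 3 samples -> removed
  lit <- cpm_filter(cd, min_cpm = 1, min_samples = 3, literal = TRUE)
  expect_false("split" %in% rownames(lit$counts))
  expect_true("expressed" %in% rownames(lit$counts))

  # every gene expressed in a single sample only: nothing reaches 3 samples
  sparse <- make_cd(diag(4) * 1e6 +
                      matrix(0, 4, 4, dimnames = list(paste0("g", 1:4),
                                                      paste0("s", 1:4))),
                    rep(c("a", "b"), each = 2))
  expect_error(cpm_filter(sparse, min_samples = 3), "all genes removed")
})

test_that("TMM factors are 1 for identical or depth-scaled libraries", {
  set.seed(71)
  base <- rnbinom(500, mu = 100, size = 10) + 1
  m <- cbind(s1 = base, s2 = base, s3 = base, s4 = base)
  rownames(m) <- paste0("g", 1:500)
  cd <- make_cd(m, c("Ctrl", "Ctrl", "4D", "4D"))
  expect_equal(unname(tmm_factors(cd)), rep(1, 4), tolerance = 1e-12)

  # pure depth difference carries no composition bias
  m2 <- cbind(s1 = base, s2 = 2 * base, s3 = base, s4 = base)
  rownames(m2) <- paste0("g", 1:500)
  f2 <- tmm_factors(make_cd(m2, c("Ctrl", "Ctrl", "4D", "4D")))
  expect_equal(unname(f2), rep(1, 4), tolerance = 1e-12)
})

test_that("TMM factors match a step-by-step trimmed-mean computation", {
  set.seed(72)
  base <- rnbinom(20, mu = 200, size = 20) + 5
  m <- cbind(s1 = base, s2 = base, s3 = base)
  m[1:2, 2] <- 8 * m[1:2, 2]        # two genes 8-fold inflated in one sample
  rownames(m) <- paste0("g", 1:20)
  cd <- make_cd(m, c("Ctrl", "Ctrl", "4D"))
  expect_equal(unname(tmm_factors(cd)), unname(tmm_oracle(m)),
               tolerance = 1e-10)

  # and on a realistic simulated matrix
  sim <- sim_counts(n_genes = 800, seed = 73)
  cd2 <- count_dataset(sim$counts, sim$samples)
  expect_equal(unname(tmm_factors(cd2)), unname(tmm_oracle(sim$counts)),
               tolerance = 1e-10)
})

test_that("TMM factors are invariant to rescaling one library", {
  # invariance is exact for the trimmed mean itself; the inverse-variance
  # weights retain a weak depth dependence, so agreement is to ~1e-3
  sim <- sim_counts(n_genes = 600, seed = 74)
  f1 <- tmm_factors(count_dataset(sim$counts, sim$samples))
  scaled <- sim$counts
  scaled[, 3] <- scaled[, 3] * 5
  f2 <- tmm_factors(count_dataset(scaled, sim$samples))
  expect_equal(unname(f1), unname(f2), tolerance = 1e-3)
})

test_that("DE engine flags planted shifts and nothing on flat genes", {
  sim <- sim_counts(n_genes = 1200, effect_log2fc = 3, nb_dispersion = 0.05,
                    seed = 75)
  cd <- cpm_filter(count_dataset(sim$counts, sim$samples))
  nf <- tmm_factors(cd)
  de4 <- de_test(cd, "4D", norm_factors = nf)
  truth <- sim$truth[match(de4$gene, sim$truth$gene), ]
  shifted4 <- truth$class %in% c("fast", "medium", "slow")
  expect_gte(mean(de4$de[shifted4]), 0.95)
  expect_lte(mean(de4$de[truth$class == "null"]), 0.01)

  # a constant gene at equal library sizes is a clean null
  m <- matrix(50, 3, 8, dimnames = list(paste0("g", 1:3), paste0("s", 1:8)))
  m[2, ] <- c(10, 12, 9, 11, 200, 190, 210, 205)
  m[3, ] <- 1000 - colSums(m[1:2, , drop = FALSE])  # equalize depth
  cdc <- make_cd(m, rep(c("Ctrl", "4D"), each = 4))
  dec <- de_test(cdc, "4D", ref = "Ctrl")
  expect_equal(dec$log2fc[1], 0)
  expect_false(dec$de[1])
  expect_true(dec$de[2])

  expect_error(de_test(cdc, "14D"), ">= 2 samples")
})

test_that("BH-adjusted FDR is a monotone step-up of the p-values", {
  sim <- sim_counts(n_genes = 500, seed = 76)
  cd <- cpm_filter(count_dataset(sim$counts, sim$samples))
  de <- de_test(cd, "4D")
  expect_true(all(de$fdr >= de$p - 1e-12))
  expect_true(all(de$fdr <= 1))
  o <- order(de$p)
  expect_true(all(diff(de$fdr[o]) >= -1e-12))
  expect_equal(de$fdr, stats::p.adjust(de$p, "BH"))
})

test_that("return-kinetics classes follow the DE-flag truth table and partition genes", {
  flag_table <- expand.grid(f4 = c(TRUE, FALSE), f14 = c(TRUE, FALSE),
                            f1 = c(TRUE, FALSE))
  map <- function(f4, f14, f1) {
    if (f4 && f14 && f1) "slow"
    else if (f4 && f14) "medium"
    else if (f4 && !f14 && !f1) "fast"
    else if (!f4 && f14 && !f1) "delayed"
    else "none"
  }
  mk <- function(flags) data.frame(gene = paste0("g", seq_along(flags)),
                                   log2fc = ifelse(flags, 2, 0.1),
                                   de = flags)
  f4 <- flag_table$f4
  f14 <- flag_table$f14
  f1 <- flag_table$f1
  got <- classify_return_kinetics(mk(f4), mk(f14), mk(f1))
  want <- mapply(map, f4, f14, f1)
  expect_equal(got$class, unname(want))
  expect_true(all(got$class %in% c("fast", "medium", "slow", "delayed",
                                   "none")))
  # directions carry the sign of the fold change where DE, 0 elsewhere
  expect_equal(got$dir_4d, ifelse(f4, 1, 0))

  bad <- mk(f4)
  bad$gene[1] <- "other"
  expect_error(classify_return_kinetics(bad, mk(f14), mk(f1)), "mismatched")
})

test_that("Poisson distances are zero for identical samples and rank groups sensibly", {
  set.seed(77)
  base <- rnbinom(400, mu = 150, size = 10) + 1
  m <- cbind(a1 = base, a2 = base, b1 = base, b2 = base)
  rownames(m) <- paste0("g", 1:400)
  res <- poisson_distance(make_cd(m, c("A", "A", "B", "B")))
  expect_equal(max(abs(res$sample_dist)), 0)
  expect_equal(unname(res$similarity), matrix(100, 2, 2))

  # group C = noisy copy of A; group B = strongly shifted
  noisy <- function(x) pmax(0, round(x * exp(rnorm(length(x), 0, 0.05))))
  shift <- base
  shift[1:100] <- shift[1:100] * 20
  m2 <- cbind(A1 = noisy(base), A2 = noisy(base),
              B1 = noisy(shift), B2 = noisy(shift),
              C1 = noisy(base), C2 = noisy(base))
  rownames(m2) <- paste0("g", 1:400)
  res2 <- poisson_distance(make_cd(m2, c("A", "A", "B", "B", "C", "C")))
  expect_true(isSymmetric(res2$group_dist))
  expect_equal(unname(diag(res2$similarity)), rep(100, 3))
  expect_gt(res2$similarity["A", "C"], res2$similarity["A", "B"])
  expect_true(all(res2$similarity >= 0 & res2$similarity <= 100))

  expect_warning(poisson_distance(make_cd(m2[, 1:3],
                                          c("A", "A", "B"))),
                 "single replicate")
})

test_that("k-means on relative profiles recovers well-separated archetypes", {
  set.seed(78)
  groups <- c("Ctrl", "4D", "14D", "1Mo")
  # four planted profile shapes over the time course, strong and up only
  shapes <- rbind(c(0, 4, 0, 0), c(0, 4, 4, 0), c(0, 4, 4, 4), c(0, 0, 4, 0))
  ari <- vapply(1:5, function(s) {
    set.seed(100 + s)
    truth <- rep(1:4, each = 50)
    mu <- 100 * 2^shapes[truth, ]
    counts <- matrix(rnbinom(200 * 8, mu = mu[, rep(1:4, each = 2)],
                             size = 100), 200, 8)
    dimnames(counts) <- list(sprintf("g%03d", 1:200),
                             paste0(rep(groups, each = 2), "_", 1:2))
    cd <- count_dataset(counts, rep(groups, each = 2))
    km <- kmeans_profiles(cd, k = 4, seed = s)
    adjusted_rand(truth, km$cluster)
  }, numeric(1))
  expect_gte(mean(ari >= 0.9), 0.8)
  expect_gte(mean(ari), 0.9)
})

test_that("k-means degenerate cases behave", {
  sim <- sim_counts(n_genes = 200, seed = 79)
  cd <- count_dataset(sim$counts, sim$samples)
  km1 <- kmeans_profiles(cd, k = 1, seed = 1)
  expect_true(all(km1$cluster == 1))
  expect_equal(km1$tot_withinss,
               sum(scale(km1$profile, scale = FALSE)^2))

  # duplicate rows always co-cluster
  counts <- cd$counts
  counts[2, ] <- counts[1, ]
  cd2 <- count_dataset(counts, sim$samples)
  km <- kmeans_profiles(cd2, k = 4, seed = 2)
  expect_equal(km$cluster[1], km$cluster[2], ignore_attr = TRUE)

  expect_error(kmeans_profiles(cd, k = 1000), "exceeds")
})

test_that("counts round-trip through TSV and the sample-table CSV", {
  sim <- sim_counts(n_genes = 50, seed = 80)
  cpath <- withr::local_tempfile(fileext = ".tsv")
  spath <- withr::local_tempfile(fileext = ".csv")
  write_counts(sim, cpath, spath)
  cd <- read_counts(cpath, spath)
  expect_equal(unname(cd$counts), unname(sim$counts))
  expect_equal(cd$samples$group, sim$samples$group)
})
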