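# microrepop

Quantitative analysis of microglial repopulation. After near-complete
pharmacological ablation (CSF1R inhibition), surviving microglia recolonize
the brain by clonal expansion, re-establish their territorial tiling, turn
the excess cells over, and gradually restore the homeostatic transcriptome.
`microrepop` implements the three quantitative tracks of that biology for
anyone working with segmented cell centroids, pulse-chase density counts, or
RNA-seq count matrices from such experiments:

1. **Spatial track** — per-cell nearest-neighbor distances (NND) and the
   fraction tiled within 50 µm; Ripley's K-function
   `K(r) = (1/n) Σᵢ Nᵢ(r)/λ` with `λ = n/|W|`, its variance-stabilized
   transform `H(r) = √(K(r)/π) − r` (zero under complete spatial
   randomness), moving-average smoothing over `[r − 15, r + 15]` µm, cluster
   *domain size* as the radius of the smoothed H maximum, and dual-color
   cluster overlap from top-10% kernel-density boundaries.
2. **Turnover track** — one-phase exponential decay
   `y(t) = (Y₀ − plateau)·e^(−kt) + plateau` fitted to EdU pulse-chase
   densities, half-life `T½ = ln 2 / k`, and OLS correlation between the
   decays of two populations.
3. **Transcriptome track** — CPM filtering, TMM normalization, per-timepoint
   differential expression versus control (|log2FC| ≥ 1 and BH-FDR < 0.05),
   classification of genes into **fast** (DE at 4 D only), **medium**
   (4 D + 14 D), **slow** (all timepoints) and **delayed** (14 D only)
   return-kinetics classes, Poisson-distance group similarity (0–100), and
   k-means (k = 4) expression clustering.

A synthetic-data module (`sim_csr`, `sim_thomas`, `sim_decay_series`,
`sim_counts`) generates point patterns, decay series and negative-binomial
count matrices with planted ground truth, so the whole pipeline is testable
without any external download.

## Worked example

```r
library(microrepop)

# clustered clonal pattern: 20 surviving clones, ~30 offspring each,
# 60 um dispersion, dual sparse labeling
pp <- sim_thomas(n_parents = 20, offspring_mean = 30, dispersion_sigma = 60,
                 seed = 42, label_probs = c(RFP = 0.5, GFP = 0.5),
                 keep_unlabeled = FALSE)
pp
#> point_pattern: 624 points in [0, 5000] x [0, 5000] um
#> labels: GFP=298, RFP=326

fraction_within(pp, 50, label = "RFP")
#> 94.5   # % of RFP+ cells with a same-color neighbor within 50 um

h <- smooth_h(k_to_h(ripley_k(pp, r = seq(0, 600, 5), label = "RFP")))
domain_size(h)
#> 190    # um: radius of the smoothed H maximum, the cluster domain scale

overlap_percent(cluster_mask(kernel_density(pp, label = "RFP")),
                cluster_mask(kernel_density(pp, label = "GFP")))
#> 6.1    # % overlap of the two channels' top-10% density clusters

# pulse-chase turnover: 4 timepoints x 5 animals, 5% measurement noise
d <- sim_decay_series(noise_sd = 5, seed = 42)
fit_decay(d$t_days, d$density_per_mm2, plateau = 0)
#> one-phase decay fit (plateau fixed): Y0 = 105.1, plateau = 0,
#> k = 0.007018 /day, T1/2 = 98.76 days, SSE = 722.4, n = 20
```

A clustered pattern shows nearly all cells tiled below 50 µm (CSR at the
same intensity would give ~50–60 µm mean spacing), a domain size of roughly
three times the offspring dispersion, and low overlap between independently
placed color channels. The decay fit recovers the generating half-life
(111.3 days) within sampling noise.

The three tracks are also available as pipeline calls — `run_spatial()`,
`run_turnover()`, `run_transcriptome()` — that write CSV reports plus a
provenance record, and as a command-line wrapper:

```sh
Rscript inst/cli/microrepop.R simulate --what counts --out sim
Rscript inst/cli/microrepop.R transcriptome --counts sim/counts.tsv \
    --samples sim/samples.csv --out results
```

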