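---
title: "Models and methods behind microrepop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind microrepop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microrepop)
```

`microrepop` quantifies three aspects of microglial recolonization after
near-complete ablation: the spatial organization of the repopulated
population, the turnover of the newborn cohort, and the kinetics with which
the homeostatic transcriptome is restored. This vignette explains the models
each track assumes, the parameters that matter, the numerical choices made
where the design was genuinely open, and what the synthetic-data tests do
and do not demonstrate about real tissue data.

## Spatial track

### Point patterns and the tiling statistic

The unit of analysis is a planar point pattern: the centroids of segmented,
labeled cells inside a rectangular observation window, in micrometres
(`point_pattern()`, `read_points()`). The window area $|W|$ fixes the
intensity estimate $\lambda = n/|W|$ used throughout. Coordinates follow the
image convention of the source CSV unchanged; every statistic in the package
is invariant to translation, rotation and axis flips, so the y-axis
direction is irrelevant and no conversion is applied.

Nearest-neighbor distances (NND) are plain Euclidean distances to the
closest other cell of the same color, with no edge correction — matching
how plugin-based NND analyses of whole sections are usually run. Homeostatic
microglia tile at roughly 50 µm spacing, so the summary statistic
`fraction_within(p, 50)` — the percentage of cells whose NND is at most
50 µm, inclusive — measures how strongly a channel is clustered at the
tiling scale. Because no correction is applied, boundary cells have slightly
inflated NNDs; at the densities and window sizes the package targets
(thousands of cells in a ~25 mm² section) the bias on the mean is a few
percent, which the CSR closed-form test ($\mathbb{E}[\mathrm{NND}] =
1/(2\sqrt\lambda)$) bounds explicitly.

### Ripley's K and the H-transform

The second-order statistic is

$$K(r) = \frac{1}{n}\sum_{i=1}^{n} \frac{N_i(r)}{\lambda},$$

with $N_i(r)$ the number of further cells within $r$ of cell $i$ — and its
variance-stabilized transform $H(r) = \sqrt{K(r)/\pi} - r$, which is zero
under complete spatial randomness, positive under clustering and negative
under dispersion.

The literal definition has no edge correction and is biased low near the
boundary, which drags $H$ negative at large radii on finite windows.
`ripley_k()` therefore exposes three estimators:

* `none` — the literal definition, kept because it is exactly checkable
  against an $O(n^2)$ enumeration (the test suite does this to
  $10^{-10}$ relative tolerance on patterns up to $n = 2000$);
* `border` — the reduced-sample estimator (outer sum restricted to points
  at least $r$ from the boundary, renormalized);
* `translation` — each pair weighted by $|W|/|W \cap W_{\text{shift}}|$,
  the default, because it is unbiased on rectangles and reproduces
  $H \approx 0$ under CSR across the full radius range. $\lambda$ is always
  the single global estimate $n/|W|$.

The default radius grid runs from 0 to a quarter of the shorter window side
in 5 µm steps; the hard precondition is $r_{\max}$ at most half the shorter
side, beyond which pair weights degenerate.

$H$ is smoothed by a moving average over grid radii in
$[r - 15, r + 15]$ µm (`smooth_h()`, half-width exposed). At the grid edges
the window truncates rather than pads — no data are invented; the first and
last few radii therefore average fewer points. Averaging is over grid
points, not a continuous integral; on a 5 µm grid the difference is
negligible relative to sampling noise. The **domain size** is the radius at
which the smoothed $H$ attains its maximum; ties break toward the smallest
radius, the conservative choice. Smoothing is enforced before the argmax,
since the raw $H$ of a sparse pattern is jagged enough to misplace the peak.

### Kernel-density cluster boundaries and overlap

Cluster territories per color are delimited by thresholding a 2D Gaussian
kernel density. The kernel scale is specified as a *variance* of 100 µm²,
i.e. $\sigma = 10$ µm — the dimensionally consistent reading of a "100 µm²
Gaussian kernel". The raster defaults to 10 µm pixels (≈ $\sigma$; finer
pixels change overlap percentages by less than the across-animal spread, at
quadratic cost). The density is the raw kernel sum at pixel centers with no
edge renormalization; away from the boundary the raster integrates to the
point count (tested to 2%). Implementation note: the isotropic kernel is
separable, so the raster is a single $n_x \times n$ by $n \times n_y$
matrix product rather than a per-pixel loop.

The cluster mask keeps the pixels above the $1 - f$ quantile of *all*
window pixels ($f = 0.10$ by default, the "top 10% density" rule). Taking
the quantile over all pixels — rather than only pixels with appreciable
density — is well defined on any grid and matches the calibration of the
threshold to expected cell density. A constant grid has no meaningful
quantile and is rejected (`threshold degenerate`).

Overlap between the two color channels' masks is reported as a percentage
under two denominators, because the field uses both phrasings of "relative
to the combined area":

* `union` (default): $100\,|A \cap B| / |A \cup B|$;
* `symmetric`: $100\,|A \cap B| / |A \,\triangle\, B|$ — intersection over
  the combined *non-overlapping* area. This ratio is unbounded; for
  identical non-empty masks it is $\infty$, which is returned as such
  rather than clamped.

Neither is asserted to be "the" published definition; the flag
`overlap_definition` switches them everywhere.

## Turnover track

EdU pulse-chase densities are modeled as one-phase exponential decay,
$y(t) = (Y_0 - P)e^{-kt} + P$, $T_{1/2} = \ln 2 / k$ — the standard model
when the labeled cohort neither proliferates nor is replenished.
`fit_decay()` uses Levenberg–Marquardt least squares with a deterministic
multi-start: the plateau starts at $\min(y)$ (or its fixed value), the rate
at the slope of a log-linear regression of $\log(y - P_0 + \varepsilon)$ on
$t$, with extra starts a decade either side; the converged fit with the
smallest SSE wins, and the refined fit provably never does worse than its
log-linear start (a property test). Observations are animal-level densities,
not group means, since each timepoint carries its own animals.

Degenerate inputs are rejected rather than coerced: constant series and
rising series give a `no decay detected` error (the rate is bounded below at
$10^{-10}$/day and a fit pinned at the bound is treated as no decay); a free
plateau needs at least three distinct timepoints, a fixed plateau two.

The plateau mode matters for identifiability. With sampling restricted to a
window on the order of one half-life (e.g. 14–120 days against a ~111-day
half-life), the plateau and rate are strongly confounded and a free-plateau
fit is noticeably biased at realistic noise; when the asymptote is known —
a decaying labeled cohort with no relabeling decays to zero — fixing
`plateau = 0` restores precise recovery. Both modes are exposed
(`plateau = "free"` fits the asymptote with a lower bound of 0), and the
package's own recovery simulations fit with the plateau fixed at the
generator's true value of 0 for exactly this reason.

`decay_correlation()` is ordinary least squares of one population's paired
densities on another's, reporting slope, intercept and $R^2$; pairing is at
the animal × timepoint level by default.

## Transcriptome track

Counts enter as a genes × samples matrix with a sample-to-group table.
Processing follows the standard count pipeline: genes are kept when they
reach ≥ 1 CPM (on raw library sizes) in ≥ 3 samples; normalization is
weighted trimmed-mean-of-M-values (TMM) with the usual 30%/5% trims,
rescaled to geometric mean 1. The keep-rule is deliberate: the removal
phrasing "less than 1 CPM in at least 3 samples" would, applied literally to
a ~19-sample design, delete almost every gene with any zero-heavy group;
the literal rule remains available as `literal = TRUE`.

Differential expression versus control is a deliberately simple, documented
engine: Welch's unequal-variance t-test on $\log_2(\text{CPM} + 0.5)$ with
TMM-effective library sizes, BH correction within each contrast, and the DE
rule $|\log_2\mathrm{FC}| \ge 1$ and FDR < 0.05. The scientific payload of
this track is the *kinetic classification*, not the test statistic, and the
classifier accepts any externally produced DE table in the same schema
(columns `gene`, `log2fc`, `de`), so a moderated-variance engine can be
substituted without touching the classification. Two exactness caveats are
worth knowing: a gene with identical counts in every sample has zero log
fold change only when library sizes are equal (CPM depends on depth), and
with both group variances zero the p-value is defined as 1 for equal means
and 0 otherwise.

The return-kinetics classes are a truth table over the three DE flags
(4 D, 14 D, 1 Mo, all versus control): fast = DE at 4 D only; medium = 4 D
and 14 D; slow = all three; delayed = 14 D only; every other combination is
`none`. The classes partition the gene universe by construction.

Group similarity uses a Poisson-model dissimilarity: libraries are scaled
to a common depth, each sample pair is scored by the root total Poisson
deviance from the pair's per-gene mean profile, and group distances average
the cross-replicate pairs. The published 0–100 "relative similarity" rescale
is not defined anywhere we could follow, so the package normalizes by the
largest off-diagonal group distance — the most dissimilar pair of groups
scores 0, identity scores 100 — and the absolute similarity values should
be read as relative to that anchor, not as portable constants.

K-means (k = 4 by default) clusters genes on the z-score of group-mean
log-CPM — relative expression shape, not magnitude; genes with a flat
profile get z = 0 rather than dividing by zero. Restarts are deterministic
given the seed, best total within-cluster sum of squares wins.

## Synthetic-data module

The generators define the conditions under which the pipeline is validated:

* `sim_csr(n, window)` — homogeneous Poisson (binomial, given $n$) points;
  the CSR null. Default window 5000 × 5000 µm ≈ a 25 mm² hemibrain
  section.
* `sim_thomas()` — a Thomas process: uniform parents, Poisson(offspring
  per parent) offspring displaced by an isotropic Gaussian
  ($\sigma$ = the planted cluster scale), clipping (not torus wrapping) at
  the window edge to mimic a tissue-section boundary. Each clone samples a
  color once (defaults 6.9% RFP / 9.9% GFP, sparse dual labeling) and all
  clone members inherit it, with the ground-truth clone id returned. The
  biology motivating this choice is clonal expansion of surviving cells;
  no mechanistic growth model is claimed beyond matching cluster summary
  statistics.
* `sim_decay_series()` — per-animal densities on the decay curve plus
  additive Gaussian noise; defaults 14/30/60/120 days, 5 animals per
  timepoint, $Y_0 = 100$ cells/mm², plateau 0, half-life 111.3 days,
  noise SD 5 (5% of $Y_0$) — the pulse-chase design scale.
* `sim_counts()` — negative-binomial counts (gene-wise constant dispersion,
  default 0.05) for Ctrl/4D/14D/1Mo × 4 replicates, library sizes
  log-uniform in $[5\times10^6, 2\times10^7]$, genes planted into the five
  kinetic archetypes (default 8/5/4/3% fast/medium/slow/delayed, 80% null)
  with ±3 log2FC shifts at the class-defining timepoints; an optional P4
  group receives the immature (4D-like) shift. Class counts are apportioned
  deterministically (largest remainder), signs are random per gene.

Every generator is reproducible bit-for-bit given its seed, with a single
explicit RNG stream per call.

What passing on these fixtures shows — and what it does not: the synthetic
patterns have ideal segmentation (no merged or missed cells), stationary
intensity (no cortical-layer gradients), sharp rectangular windows (no
ventricles or tissue tears), Gaussian measurement noise, and NB counts with
constant dispersion (no outlier samples, batch effects or length biases).
Recovery of planted truth under these conditions validates the estimators
and the pipeline plumbing; it does not certify performance under
segmentation artifacts or structured biological heterogeneity, which should
be assessed on the real data they occur in.

## Validation scale and determinism

The test suite validates each operation against hand-computed examples and
independent brute-force oracles (literal $O(n^2)$ K, pairwise-loop NND,
step-by-step trimmed-mean TMM), and runs the statistical recovery checks at
the study's own scale: 200 CSR patterns of $n = 2000$ in a 5000 µm window
for the H null (pointwise 5-SEM envelope around zero), 50 Thomas patterns
per cluster scale $\sigma \in \{30, 60, 120\}$ µm for domain-size recovery
(medians within ±25% of the oracle and monotone in $\sigma$), 200 noisy
decay series for half-life recovery (median error ≤ 15%, exact at zero
noise), and 2000-gene matrices for classification (balanced accuracy ≥ 90%;
all-null matrices ≤ 5% false DE). These sizes are the package's chosen
validation conditions and are reported alongside each value by
`scripts/acceptance.R`.

## Known limitations

* K/H is univariate per color; cross-color interaction is measured only
  through KDE-mask overlap, not a bivariate K.
* No inhomogeneous-intensity correction: a density gradient across the
  window reads as clustering.
* NND carries no edge correction (documented bias, small at target scales).
* The DE engine has no variance moderation, so it is conservative at very
  small replicate numbers relative to empirical-Bayes engines; use the
  external-table route when that matters.
* Confidence intervals for decay parameters are not computed; the fit
  reports point estimates and SSE.
* The Poisson-distance similarity scale is anchored to the most dissimilar
  group pair in the data set at hand and is not comparable across data
  sets.
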