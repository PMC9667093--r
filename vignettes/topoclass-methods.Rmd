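---
title: "Graph-topology classification of two-group connectomes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-topology classification of two-group connectomes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis this package implements

topoclass implements a complete graph-theory + machine-learning pipeline for
discriminating two subject groups (e.g. patients vs healthy controls) from
resting-state functional connectomes, together with a synthetic cohort
generator that provides ground-truthed data for validating every stage.

The chain is:

1. **Connectivity.** Each subject contributes a timepoints × nodes matrix of
   regional time series. Edges are Pearson correlations between node pairs,
   variance-stabilized by Fisher's r-to-z (`pearson_matrix()`, `fisher_z()`).
2. **Binary graphs over a sparsity grid.** The z-matrix is binarized at
   sparsity levels S = 0.05, 0.10, …, 0.50 (10 levels): at each S exactly
   `round(S · n(n−1)/2)` edges are kept — the top-ranked entries of the
   upper triangle (`binarize_stack()`). Because ranking is order-based, the
   graphs are identical whether built from r or z, and the edge sets are
   nested across the grid.
3. **Topological metrics.** Seven global metrics (Cp, Lp, γ, λ, σ, Eglobal,
   Elocal) and five nodal metrics (NCp, Ne, NLe, DC, BC) per threshold
   (`compute_metric_panel()`). γ and λ normalize Cp and Lp by their means
   over an ensemble of degree-preserving rewired null graphs; σ = γ/λ.
4. **Features.** Per-threshold values plus the trapezoidal area under each
   metric's curve across the grid (AUC features). For n nodes and L
   thresholds this yields 5·n·(L+1) + 7·(L+1) columns — 8,877 for a
   160-node atlas (`assemble_features()`).
5. **Selection cascade** on the training split only: two-sided Mann-Whitney
   screen at p < 0.01; greedy Spearman collinearity pruning (a later column
   is dropped when |ρ| > 0.7 with a retained earlier column);
   standardization fitted on training rows; squared-error LASSO on the 0/1
   labels with the shrinkage weight chosen by stratified fivefold
   cross-validation (`select_features()`).
6. **Classifiers.** Linear/RBF SVM, L1-regularized logistic regression,
   random forest, and Gaussian naive Bayes, each tuned by exhaustive grid
   search under stratified 10-fold cross-validation on the training split
   and scored on the held-out 30% (`run_loops()`); the whole procedure is
   repeated over stratified 70/30 resamples (100 outer loops at full
   scale), reporting mean ± SD of accuracy, balanced accuracy, sensitivity,
   specificity and ROC AUC.
7. **Significance and follow-up.** A label-shuffling permutation test
   re-runs the complete pipeline per shuffle (`permutation_test()`,
   p = (#{permuted ≥ actual}+1)/(B+1)); features selected in more than 80%
   of loops form the stable set (`feature_stability()`); stable features
   are related to clinical scores within the patient group by partial
   Pearson correlation with demographic/psychometric covariates and
   Bonferroni correction (`correlate_clinical()`); demographic tables use
   a Kolmogorov-Smirnov normality gate, Welch t or rank-sum tests, and
   chi-squared for binary variables (`demographic_table()`).

# The synthetic cohort generator

Real resting-state fMRI for this problem is not publicly deposited, so the
package ships a generator whose defaults emulate the study conditions this
pipeline targets: two groups of 101 and 105 subjects, a 160-node atlas
partitioned into six subnetworks with the canonical
cerebellum/sensorimotor/occipital/cingulo-opercular/default/fronto-parietal
proportions (18/33/22/32/34/21), and 230 retained timepoints per subject
(240 acquired minus 10 discarded for signal stabilization).

**Base covariance.** Within each subnetwork, nodes sit on a ring lattice
(6 neighbours) whose edges carry weight 0.30; each lattice edge is rewired
with probability 0.10 to a uniformly random node, keeping its strength —
the Watts-Strogatz construction that produces the γ > 1, λ ≈ 1 small-world
regime the metrics assume. All remaining node pairs carry a weak jittered
background weight of 0.08. The dense background is deliberate: downstream
binarization is *rank-based*, so a planted multiplicative change can only
express itself if the affected edges have competitors above zero. With a
sparse base (exact zeros off the lattice), up-scaling a node's row cannot
add edges at any threshold and the planted "increase" is invisible — or
worse, reversed by a sampling artifact. With the dense background, planted
effects move degree in the intended direction at every threshold.
Positive definiteness is restored by diagonal loading and rescaling to a
correlation matrix.

**Planted effects.** An `effect_plan()` scales the off-diagonal entries
incident to designated nodes: by default 4 cerebellum nodes down (factor
1 − δ) and 3 sensorimotor + 2 occipital nodes up (factor 1 + δ),
mirroring the direction and placement of the discriminative alterations
reported for essential tremor. δ = 0 makes the groups exchangeable by
construction. Multiplicative (not additive) scaling guarantees that zero
or negative entries never flip sign spuriously.

**Sampling.** Each subject's time series is multivariate normal with the
group covariance, plus white measurement noise whose standard deviation is
drawn per subject from 1.2–1.8 (relative to unit signal variance). No
autocorrelation or physiological-noise model is included: the pipeline is
correlation-based and rank-driven, so marginal distribution shape and
temporal ordering are immaterial to every downstream statistic. The noise
level is calibrated so that the default planted effect (δ = 0.4) supports
held-out accuracies in the mid-0.8s with ROC AUC ≈ 0.92 — the operating
regime reported for connectome-based classification of essential tremor —
rather than a trivially separable cohort. At near-zero noise the same
cohort classifies at ~0.99, which validates nothing interesting.

**Clinical coupling.** For group-1 subjects the tremor score `trs_ab` is
`23.6 − 5·z(w) + N(0, 5)`, where `w` is the subject's realized mean
correlation at a designated affected node (computed from that subject's own
generated time series, not from the population covariance) and `z(·)`
standardizes across the group. The negative slope plants the
anticorrelation that the partial-correlation stage should recover. Other
covariates (age, sex, education, head motion, HDRS-17, HARS-14, MMSE) are
drawn group-matched; a `plant_mmse_effect` switch adds a small MMSE
deficit in group 1 to exercise the demographic table.

# Numerical and design choices

* **Edge ranking.** Binarization ranks signed z descending (strongest
  positive correlations first); `rank = "absolute"` is available. Ties at
  the cutoff break lexicographically on the (row, column) upper-triangle
  index, so graphs are bit-reproducible across platforms.
* **Disconnected graphs.** Lp averages finite distances only (sparse
  thresholded graphs are routinely disconnected); efficiencies use
  1/∞ = 0. An edgeless graph is an error for Lp.
* **Cp convention.** Cp is the unweighted mean of nodal clustering with
  degree-<2 nodes contributing 0 — not the triangle/triplet ratio.
* **Null ensemble.** Degree-preserving double-edge swaps (10 accepted
  swaps per edge), 100 rewired graphs per (subject, threshold) at full
  scale, each seeded deterministically from the master seed. For very
  sparse small graphs a rewired ensemble can contain no triangles at all;
  the metric panel then substitutes the Erdős–Rényi expectation
  mean(k)/(n−1) for the γ denominator instead of aborting (the standalone
  `small_world_indices()` keeps the strict error as its default contract).
  At 160-node scale the fallback never triggers.
* **LASSO.** The selection LASSO is the squared-error (regression) form on
  0/1 labels — the printed loss of the procedure — not logistic LASSO;
  classification happens downstream. The λ grid has 50 log-spaced points
  from λ_max (the smallest all-zero λ) down three decades; λ_opt minimizes
  mean CV squared error with ties resolved toward the sparser model. The
  solver follows the exact piecewise-linear solution path (LARS-style
  homotopy on the active-set stationarity system) with a coordinate-descent
  fallback; it is verified against an independent reference implementation
  and against the orthonormal-design soft-threshold closed form in the
  test suite.
* **Mann-Whitney screen.** Tie-corrected normal approximation without
  continuity correction, exact enumeration when both groups have ≤ 8
  subjects and no ties. The screen, and Spearman pruning, run on a
  single-sort vectorized midrank kernel because the permutation test
  re-runs them thousands of times.
* **Splits and seeds.** Per-group test counts round half up; outer loop k
  uses split seed `master_seed + k`, so any loop can be reproduced alone.
  Every stochastic step (cohort, rewiring, folds, shuffles) takes an
  explicit seed and restores the caller's RNG state.
* **Empty selections.** An outer loop whose cascade selects nothing is
  skipped and logged, and summary denominators shrink accordingly. Inside
  the permutation test, however, empty-selection shuffles are *kept* and
  scored as a majority-class/chance model: dropping them would censor the
  low end of the null distribution and bias p towards significance.
* **Permutation scope.** Each shuffle runs the complete pipeline
  (selection, tuning, held-out scoring) on one stratified split; p-values
  use add-one smoothing and the conservative ≥ comparison.
* **Partial correlation.** Residual-correlation form with intercept;
  p from t with n − k − 2 degrees of freedom. Constant covariate columns
  are aliased with the intercept and dropped (so a constant covariate
  reproduces plain Pearson); any other rank deficiency is an error naming
  the collinear columns.
* **Demographic table.** Welch (unequal-variance) t is the default because
  it reproduces published two-decimal statistics computed from group
  summaries (−3.69 for the MMSE contrast; the pooled form gives −3.70);
  `welch_t_summary()` accepts summary-only input for exactly that check.
  The Bonferroni divisor is the number of feature × score tests actually
  performed.
* **Spearman-then-standardize order.** Standardization happens after
  pruning; since Spearman is rank-based the order cannot change the
  pruning result, so only one order is implemented.

# Problem sizes used by the tests and the acceptance script

Validation runs at desk scale, chosen to finish on one CPU in minutes
while preserving every qualitative property of the full-scale analysis:
60-node atlases with 40 + 40 subjects and 230 timepoints for the
calibration (δ = 0) and recovery (δ = 0.4) cohorts, 20 outer loops,
16 rewired null graphs per (subject, threshold); the permutation-validity
experiment uses a 20-node, 16 + 16 cohort with 99 shuffles per test and
100 meta-replicates, with the logistic-regression model at 3 inner CV
folds. Oracle equivalence of the graph metrics is checked exhaustively
(Floyd–Warshall distances, triangle enumeration, geodesic counting)
on 200 random graphs with up to 9 nodes, where brute force is exact.

# What passing tests do and do not show

The generator produces stationary Gaussian series with a block
small-world correlation structure, node-local multiplicative group
effects, and a linear clinical coupling. It does not emulate
autocorrelated BOLD dynamics, head-motion artifacts, physiological noise,
registration error, or site effects, and the planted effects are
node-incident and multiplicative rather than edge-specific. Passing the
suite therefore demonstrates that the pipeline's statistics are computed
correctly, that it is calibrated under the null, and that it recovers
recoverable signal — not that any particular clinical classification
result would replicate on real fMRI.

A known behaviour worth understanding when interpreting stability
reports: when many features carry the same group signal (strong effects,
small atlases, spillover onto module neighbours), the LASSO support
flips between near-equivalent representatives across resampling loops.
Per-feature selection frequencies then concentrate only for families with
few redundant alternates, while the *union* of a planted family's
features can be selected in every loop. At desk scale the two-node
occipital family exhibits exactly this: its members' union is selected in
100% of loops, but no single member crosses the 80% stability bar. This
is a property of L1 selection among correlated predictors — the same
mechanism that makes any single stable-feature list from such pipelines,
including published ones, an underestimate of the discriminative feature
set.

# Known limitations

* Binary, undirected, unweighted graphs only; no weighted or signed
  metrics, no modularity or participation coefficient.
* The permutation test uses one stratified split per shuffle rather than
  the full outer-loop average per shuffle; the documented full setting
  (1,000 shuffles × pipeline) is available but slow by construction.
* Random-forest tuning covers the number of trees only; naive Bayes has
  no tunables.
* The generator's six-subnetwork proportions follow the canonical
  160-node functional parcellation; other atlas sizes allocate
  proportionally (largest remainder), which is an approximation.
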