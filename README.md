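# topoclass

Graph-topology feature pipelines for two-group classification of
resting-state functional connectomes.

Clinical neuroimaging groups increasingly ask whether a disorder can be
recognized in an *individual* brain network rather than in group-average
contrasts. The standard recipe — used, for example, to separate essential
tremor patients from healthy controls — is: build each subject's binary
brain graph at many sparsity thresholds, describe it with global and nodal
graph-theory metrics, and feed those metrics as features into a
cross-validated machine-learning cascade. topoclass implements that entire
chain as tested, reusable R functions, together with a synthetic cohort
generator with planted ground truth, so every stage can be validated
end-to-end without access to patient data.

## The method

For each subject with node time series `X` (timepoints × nodes):

- edges are Pearson correlations, Fisher z-transformed:
  `z = atanh(r)`;
- the z-matrix is binarized over the sparsity grid
  S = 0.05, 0.10, …, 0.50, keeping exactly `round(S·n(n−1)/2)` top-ranked
  edges per level (edge sets are nested across the grid);
- on each graph: clustering coefficient Cp, characteristic path length Lp,
  normalized clustering γ = Cp/⟨Cp_rand⟩ and path length λ = Lp/⟨Lp_rand⟩
  against degree-preserving rewired null graphs, small-worldness σ = γ/λ,
  global and local efficiency (Eglobal, Elocal), and nodal NCp, Ne, NLe,
  degree centrality DC, and betweenness BC;
- features are every metric at every threshold plus each metric's
  trapezoidal area under the curve across the grid:
  `5·n·(L+1) + 7·(L+1)` columns — **8,877** for a 160-node atlas;
- per stratified 70/30 resample: Mann-Whitney screen (p < 0.01), greedy
  Spearman pruning (|ρ| > 0.7), standardization, and squared-error LASSO
  `L = Σᵢ(yᵢ − ŷᵢ)² + λΣⱼ|βⱼ|` with fivefold cross-validated λ — then
  SVM, L1 logistic regression, random forest and Gaussian naive Bayes,
  each tuned by grid search under 10-fold CV and scored on the held-out
  split;
- significance by label-shuffling permutation
  (`p = (#{permuted ≥ actual} + 1)/(B + 1)`), feature stability by
  selection frequency across the outer loops (stable: > 80% of loops), and
  clinical follow-up by partial Pearson correlation with covariates and
  Bonferroni correction.

## Worked example

A synthetic cohort with a planted effect of size δ = 0.4 — four cerebellum
nodes scaled down, three sensorimotor and two occipital nodes scaled up,
and a tremor score negatively coupled to the first cerebellum node's
connectivity:

```r
library(topoclass)

atl  <- atlas_spec(60)
plan <- effect_plan(atl, delta = 0.4)
coh  <- sample_cohort(atl, plan, n_group1 = 40, n_group0 = 40,
                      n_timepoints = 230, seed = 1)
#> synthetic_cohort: 80 subjects (40 group 1, 40 group 0), 60 nodes,
#>                   230 timepoints, delta = 0.40

panel <- compute_metric_panel(coh, n_random = 16, seed = 1)
round(colMeans(panel$global[, "0.25", ]), 3)
#>      Cp      Lp   gamma  lambda   sigma Eglobal  Elocal
#>   0.313   1.785   1.148   1.005   1.143   0.619   0.600

ft  <- assemble_features(panel, coh$covariates$group)
#> feature_table: 80 subjects x 3377 features
res <- run_loops(ft, models = default_models(), n_loops = 20, master_seed = 1)
res
#> loop_results: 20 completed loops (0 skipped)
#>   svm  accuracy 0.775 +/- 0.077, balanced 0.775, AUC 0.868
#>   lr   accuracy 0.762 +/- 0.077, balanced 0.762, AUC 0.836
#>   rf   accuracy 0.792 +/- 0.062, balanced 0.792, AUC 0.878
#>   gnb  accuracy 0.754 +/- 0.074, balanced 0.754, AUC 0.811
```

γ > 1 with λ ≈ 1 says the generated connectomes live in the small-world
regime the metrics assume; all four classifiers separate the groups well
above chance (a δ = 0 cohort runs at balanced accuracy ≈ 0.5).

```r
feature_stability(res, ft = ft)
#> stability_report: 2 stable features (count > 16 of 20 loops)
#>              feature count  mean_weight direction
#>   Ne_thr0.05_node021    20  0.092908552         1
#>  NCp_thr0.05_node009    18  0.029032587         1

correlate_clinical(ft, "aDC_node001", coh$covariates, scores = "trs_ab")
#>       feature  score      r        p p_threshold significant
#> 1 aDC_node001 trs_ab -0.694 7.66e-06        0.05        TRUE
```

The stable features sit at planted nodes (node 21: occipital, scaled up;
node 9: sensorimotor, scaled up) with the planted direction, and the
degree-centrality AUC feature of the coupled node recovers the planted
negative tremor-score correlation after controlling for age, sex,
education, head motion and psychometric covariates.

Published demographic statistics can be checked from summary data alone:

```r
welch_t_summary(28.44, 1.36, 101, 29.10, 1.20, 105)$t  # MMSE contrast
#> [1] -3.688067   # rounds to -3.69
```

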