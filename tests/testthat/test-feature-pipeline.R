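test_that("AUC over thresholds is the exact trapezoid", {
  g <- threshold_grid()
  expect_equal(auc_over_thresholds(rep(3, 10), g), 0.45 * 3)
  expect_equal(auc_over_thresholds(as.numeric(g), g), 0.12375)
  expect_equal(auc_over_thresholds(rep(0, 10), g), 0)
  expect_error(auc_over_thresholds(rep(1, 9), g), "one finite")
})

test_that("feature count obeys the closed form 5n(L+1) + 7(L+1)", {
  ft <- fixture_effect_features()
  n <- 30L
  expect_identical(ncol(ft$x), 5L * n * 11L + 7L * 11L)  # 1727
  expect_false(anyDuplicated(colnames(ft$x)) > 0)
  # canonical naming
  expect_true(all(c("Eglobal_thr0.20", "aCp", "DC_thr0.35_node012",
                    "aDC_node012", "aBC_node030") %in% colnames(ft$x)))
  # for the 160-node atlas the same formula gives 8,877
  expect_identical(5L * 160L * 11L + 7L * 11L, 8877L)
})

test_that("constant metrics produce AUC columns equal to 0.45 x value", {
  grid <- threshold_grid()
  glob <- array(1, c(1, 10, 7),
                dimnames = list("s1", topoclass:::format_threshold(as.numeric(grid)),
                                topoclass:::global_metric_names))
  noda <- array(1, c(1, 10, 5, 3),
                dimnames = list("s1", topoclass:::format_threshold(as.numeric(grid)),
                                topoclass:::nodal_metric_names,
                                paste0("n", 1:3)))
  panel <- structure(list(global = glob, nodal = noda, grid = grid,
                          subjects = "s1", node_labels = paste0("n", 1:3)),
                     class = "metric_panel")
  ft <- assemble_features(panel)
  expect_equal(unname(ft$x[1, "aCp"]), 0.45)
  expect_equal(unname(ft$x[1, "aNLe_node002"]), 0.45)
  # missing cell is reported by name
  glob[1, 2, 1] <- NA
  panel$global <- glob
  expect_error(assemble_features(panel), "missing metric cell")
})

test_that("stratified splits hit the rounded per-group test counts", {
  groups <- c(rep(1, 101), rep(0, 105))
  sp <- stratified_split(groups, 0.30, seed = 1)
  expect_identical(sum(groups[sp$test] == 1), 30L)   # round(30.3)
  expect_identical(sum(groups[sp$test] == 0), 32L)   # round-half-up(31.5)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(groups))
  sp2 <- stratified_split(groups, 0.30, seed = 1)
  expect_identical(sp, sp2)
  expect_error(stratified_split(groups, 0), "test_frac")
  expect_error(stratified_split(c(1, 0, 0), 0.3), "at least 2")
})

test_that("the rank-sum screen reproduces exact and approximate references", {
  # separated ranks {1,2,3} vs {4,5,6}: exact two-sided p = 2/20 = 0.1
  x <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)
  res <- mannwhitney_screen(x, c(1, 1, 1, 0, 0, 0), alpha = 0.2)
  expect_equal(unname(res$p[1]), 0.1)
  expect_true(res$survivors[1])

  # constant feature: p = 1, never survives
  xc <- cbind(rep(1, 20), rnorm(20))
  resc <- mannwhitney_screen(xc, rep(c(0, 1), 10), alpha = 0.99)
  expect_equal(unname(resc$p[1]), 1)
  expect_false(resc$survivors[1])

  # large-sample approximation matches wilcox.test (tie-corrected, no cc)
  set.seed(31)
  g <- rep(c(0, 1), each = 30)
  xm <- cbind(rnorm(60), rnorm(60) + g, round(rnorm(60), 1))  # col 3 has ties
  res2 <- mannwhitney_screen(xm, g, alpha = 0.01)
  for (j in 1:3) {
    ref <- suppressWarnings(
      wilcox.test(xm[g == 1, j], xm[g == 0, j], correct = FALSE,
                  exact = FALSE)$p.value)
    expect_equal(unname(res2$p[j]), ref, tolerance = 1e-10)
  }
  # a feature tracking the label survives at alpha = 0.01
  expect_true(res2$survivors[2])
})

test_that("Spearman pruning removes later collinear columns and logs partners", {
  set.seed(41)
  a <- rnorm(100)
  x <- cbind(f1 = a, f2 = a, f3 = rnorm(100), f4 = rank(a) + rnorm(100, 0, 1e-8))
  pr <- spearman_prune(x, rep(TRUE, 4), cutoff = 0.7)
  expect_identical(pr$kept, c("f1", "f3"))
  expect_identical(pr$removed$feature, c("f2", "f4"))
  expect_identical(pr$removed$partner, c("f1", "f1"))
  expect_equal(pr$removed$rho[1], 1)

  # independent noise columns survive together
  set.seed(42)
  xn <- matrix(rnorm(100 * 5), 100, 5,
               dimnames = list(NULL, paste0("n", 1:5)))
  prn <- spearman_prune(xn, rep(TRUE, 5), cutoff = 0.7)
  expect_identical(prn$kept, paste0("n", 1:5))

  # of three mutually correlated columns only the first survives
  b <- rnorm(200)
  x3 <- cbind(c1 = b + rnorm(200, 0, 0.1), c2 = b + rnorm(200, 0, 0.1),
              c3 = b + rnorm(200, 0, 0.1))
  pr3 <- spearman_prune(x3, rep(TRUE, 3), cutoff = 0.7)
  expect_identical(pr3$kept, "c1")
})

test_that("standardization is fitted on training rows and applied to new data", {
  set.seed(51)
  xtr <- matrix(rnorm(40 * 3, mean = 5, sd = 2), 40, 3,
                dimnames = list(NULL, c("a", "b", "c")))
  sc <- feature_scaler(xtr)
  z <- apply_scaler(sc, xtr)
  expect_equal(colMeans(z), c(a = 0, b = 0, c = 0), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), c(a = 1, b = 1, c = 1))
  expect_identical(apply_scaler(sc, xtr), z)
  shifted <- xtr + 3
  expect_equal(colMeans(apply_scaler(sc, shifted)),
               3 / apply(xtr, 2, sd), ignore_attr = TRUE)
  xtr[, 2] <- 7
  expect_error(feature_scaler(xtr), "zero-variance.*b")
})

test_that("column midranks agree with rank() on tied and untied data", {
  set.seed(55)
  x <- cbind(rnorm(30), round(rnorm(30), 0), rep(2, 30), rpois(30, 3))
  rk <- topoclass:::col_midranks(x)
  for (j in 1:4) {
    expect_equal(rk$ranks[, j], rank(x[, j]))
    t <- table(x[, j])
    expect_equal(rk$tie_terms[j], sum(t^3 - t), ignore_attr = TRUE)
  }
})

test_that("the coordinate-descent LASSO path matches glmnet", {
  set.seed(57)
  n <- 45; p <- 8
  X <- scale(matrix(rnorm(n * p), n, p))
  colnames(X) <- paste0("x", 1:p)
  y <- as.numeric(X %*% c(1.5, -1, 0.5, rep(0, p - 3)) + rnorm(n, 0, 0.7) > 0)
  lam <- exp(seq(log(0.3), log(0.003), length.out = 12))
  ours <- lasso_path(X, y, lam)
  ref <- glmnet::glmnet(X, y, family = "gaussian", alpha = 1,
                        lambda = sort(lam, decreasing = TRUE),
                        standardize = FALSE, thresh = 1e-12)
  expect_equal(unname(ours$beta), unname(as.matrix(ref$beta)),
               tolerance = 1e-5)
  expect_equal(ours$intercept, unname(ref$a0), tolerance = 1e-5)
})

test_that("LASSO shrinkage limits match closed forms", {
  set.seed(61)
  n <- 40; p <- 5
  # centred orthonormal design scaled so X'X = n I
  X <- qr.Q(qr(scale(matrix(rnorm(n * p), n, p), scale = FALSE))) * sqrt(n)
  colnames(X) <- paste0("x", 1:p)
  beta_true <- c(2, -1.5, 0.8, 0, 0)
  y01 <- as.numeric(X %*% beta_true + rnorm(n, 0, 0.5) > 0)

  # huge lambda: all coefficients zero, intercept = label mean
  expect_warning(
    res_big <- lasso_select(X, y01, lambda_grid = c(1e6), cv_folds = 2,
                            seed = 1),
    "no features")
  expect_true(all(res_big$beta == 0))
  expect_equal(res_big$intercept, mean(y01), tolerance = 1e-6)

  # soft-threshold oracle on the orthonormal design at fixed lambda
  lam <- 0.05
  res <- lasso_select(X, y01, lambda_grid = c(lam * 2, lam), cv_folds = 2,
                      seed = 1)
  uni <- as.numeric(crossprod(X, y01 - mean(y01))) / n
  soft <- sign(uni) * pmax(abs(uni) - res$lambda_opt, 0)
  expect_equal(unname(res$beta), soft, tolerance = 1e-4)

  # near-zero lambda on a full-rank design approaches OLS
  set.seed(62)
  X2 <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, paste0("v", 1:3)))
  y2 <- as.numeric(X2[, 1] - X2[, 2] + rnorm(50, 0, 0.3) > 0)
  res0 <- lasso_select(X2, y2, lambda_grid = c(1e-6, 1e-7), cv_folds = 2,
                       seed = 2)
  ols <- coef(lm(y2 ~ X2))
  expect_equal(unname(res0$beta), unname(ols[-1]), tolerance = 1e-4)
})

test_that("the selection cascade nests its stages and never touches test rows", {
  ft <- fixture_effect_features()
  sp <- stratified_split(ft$groups, 0.3, seed = 8)
  tr <- select_features(ft, sp$train, seed = 8)
  expect_true(all(tr$selected %in% tr$spearman$kept))
  expect_true(all(tr$spearman$kept %in% tr$utest_survivors))

  # leakage guard: delete all test rows and recompute — identical results
  ft2 <- ft
  ft2$x <- ft$x[sp$train, , drop = FALSE]
  ft2$groups <- ft$groups[sp$train]
  ft2$subjects <- ft$subjects[sp$train]
  tr2 <- select_features(ft2, seq_along(sp$train), seed = 8)
  expect_identical(tr$utest_p, tr2$utest_p)
  expect_identical(tr$spearman, tr2$spearman)
  expect_equal(tr$lasso$lambda_opt, tr2$lasso$lambda_opt)
  expect_equal(tr$lasso$beta, tr2$lasso$beta)
  expect_identical(tr$selected, tr2$selected)
})

test_that("planted-effect features are recovered by the cascade", {
  ft <- fixture_effect_features()
  coh <- fixture_effect_cohort()
  plan <- coh$truth$plan
  affected <- c(plan$affected_down, plan$affected_up)
  node_tags <- sprintf("node%03d", affected)
  sp <- stratified_split(ft$groups, 0.3, seed = 3)
  tr <- select_features(ft, sp$train, seed = 3)
  sel_nodes <- regmatches(tr$selected, regexpr("node[0-9]+", tr$selected))
  expect_gt(length(intersect(sel_nodes, node_tags)), 0)
})
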