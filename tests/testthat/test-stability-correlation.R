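make_fake_loops <- function(sets, skipped = integer(0)) {
  loops <- lapply(seq_along(sets), function(k) {
    list(selected = sets[[k]], empty_selection = k %in% skipped,
         trace = list(lasso = list(beta = stats::setNames(
           rep(0.5, length(sets[[k]])), sets[[k]]))))
  })
  structure(list(loops = loops, skipped = skipped,
                 n_completed = length(sets) - length(skipped),
                 models = "lr", summary = list()),
            class = "loop_results")
}

test_that("stability uses a strict count threshold over completed loops", {
  sets <- c(replicate(100, "always", simplify = FALSE))
  sets <- lapply(seq_len(100), function(k) {
    c("always", if (k <= 80) "boundary", if (k <= 81) "over")
  })
  rep <- feature_stability(make_fake_loops(sets), threshold = 80)
  expect_true("always" %in% rep$stable)
  expect_true("over" %in% rep$stable)        # 81 > 80
  expect_false("boundary" %in% rep$stable)   # exactly 80 is not stable
  expect_identical(rep$counts$count[rep$counts$feature == "boundary"], 80L)
  # counts can never exceed completed loops
  expect_true(all(rep$counts$count <= rep$n_completed))
  # default threshold scales with completed loops (80%)
  rep2 <- feature_stability(make_fake_loops(sets[1:10]))
  expect_equal(rep2$threshold, 8)
})

test_that("skipped loops are excluded from stability denominators", {
  sets <- lapply(1:10, function(k) if (k <= 2) character(0) else "f1")
  rep <- feature_stability(make_fake_loops(sets, skipped = 1:2),
                           threshold = 6)
  expect_identical(rep$n_completed, 8L)
  expect_identical(rep$counts$count[1], 8L)
  expect_true("f1" %in% rep$stable)
})

test_that("partial correlation equals reference formulations", {
  set.seed(111)
  n <- 50
  Z <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("z1", "z2", "z3")))
  x <- Z %*% c(1, -1, 0.5) + rnorm(n)
  y <- Z %*% c(0.5, 0.3, -1) + 0.6 * x + rnorm(n)
  pc <- partial_pearson(x, y, Z)
  expect_equal(pc$r, oracle_partial_cor(x, y, Z), tolerance = 1e-10)
  expect_identical(pc$df, n - 3 - 2)

  # no covariates: plain Pearson r and its t-test p
  pc0 <- partial_pearson(x, y, NULL)
  ref <- cor.test(x, y)
  expect_equal(pc0$r, unname(ref$estimate))
  expect_equal(pc0$p, ref$p.value, tolerance = 1e-10)

  # y = x shares residuals entirely
  expect_equal(partial_pearson(x, x + 0, Z)$r, 1)

  # a constant covariate adds nothing beyond the intercept
  pc_const <- partial_pearson(x, y, cbind(const = rep(2, n)))
  expect_equal(pc_const$r, pc0$r)
  expect_equal(pc_const$p, pc0$p)

  # duplicated covariates are a named failure
  expect_error(partial_pearson(x, y, cbind(a = Z[, 1], b = Z[, 1])),
               "rank-deficient")
})

test_that("Bonferroni flags are non-increasing in the number of tests", {
  set.seed(121)
  n <- 60
  covs <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5),
                     education = rnorm(n), fd_power = abs(rnorm(n)),
                     hdrs17 = rpois(n, 2), hars14 = rpois(n, 2),
                     mmse = rnorm(n, 28), trs_ab = rnorm(n, 20, 5),
                     trs_c = rnorm(n, 12, 4), tetras = rnorm(n, 21, 6))
  x <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("feat", 1:4)))
  x[, 1] <- -2 * covs$trs_ab + rnorm(n, 0, 3)
  ft <- structure(list(x = x, groups = rep(1L, n),
                       subjects = as.character(1:n)),
                  class = "feature_table")
  all4 <- correlate_clinical(ft, paste0("feat", 1:4), covs, alpha = 0.05)
  one <- correlate_clinical(ft, "feat1", covs, scores = "trs_ab", alpha = 0.05)
  expect_equal(unique(one$p_threshold), 0.05)  # single test: no correction
  expect_lt(unique(all4$p_threshold), 0.05)
  expect_lte(sum(all4$significant), sum(all4$p < 0.05))
  # the planted anticorrelation is flagged with r < 0
  hit <- all4[all4$feature == "feat1" & all4$score == "trs_ab", ]
  expect_true(hit$significant)
  expect_lt(hit$r, 0)
})

test_that("clinical correlation under a zero slope is calibrated", {
  set.seed(131)
  n <- 60
  flags <- replicate(20, {
    covs <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5),
                       education = rnorm(n), fd_power = abs(rnorm(n)),
                       hdrs17 = rpois(n, 2), hars14 = rpois(n, 2),
                       mmse = rnorm(n, 28), trs_ab = rnorm(n, 20, 5))
    x <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    ft <- structure(list(x = x, groups = rep(1L, n),
                         subjects = as.character(1:n)),
                    class = "feature_table")
    res <- correlate_clinical(ft, paste0("f", 1:5), covs, scores = "trs_ab",
                              alpha = 0.05, n_tests = 1)  # nominal level
    mean(res$significant)
  })
  expect_lte(mean(flags), 0.10)
})

test_that("Welch t from summaries reproduces published two-decimal statistics", {
  mmse <- welch_t_summary(28.44, 1.36, 101, 29.10, 1.20, 105)
  expect_equal(round(mmse$t, 2), -3.69)
  age <- welch_t_summary(46.49, 14.75, 101, 45.03, 13.14, 105)
  expect_equal(round(age$t, 2), 0.75)
  same <- welch_t_summary(5, 1, 30, 5, 1, 30)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("summary-based Welch t equals raw-sample Welch t by construction", {
  set.seed(141)
  for (i in 1:5) {
    n1 <- sample(10:40, 1); n2 <- sample(10:40, 1)
    m1 <- rnorm(1); m2 <- rnorm(1); s1 <- runif(1, 0.5, 2); s2 <- runif(1, 0.5, 2)
    mk <- function(n, m, s) { z <- rnorm(n); m + s * (z - mean(z)) / sd(z) }
    x1 <- mk(n1, m1, s1); x2 <- mk(n2, m2, s2)
    ref <- t.test(x1, x2, var.equal = FALSE)
    ours <- welch_t_summary(m1, s1, n1, m2, s2, n2)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("demographic tables gate tests by type and normality", {
  set.seed(151)
  n1 <- 60; n0 <- 70
  covs <- data.frame(
    group = c(rep(1, n1), rep(0, n0)),
    age = c(rnorm(n1, 46, 14), rnorm(n0, 45, 13)),
    sex = c(rbinom(n1, 1, 0.45), rbinom(n0, 1, 0.55)),
    skewed = c(rexp(n1, 1), rexp(n0, 0.5)),
    all_na = NA_real_
  )
  expect_message(tab <- demographic_table(covs), "all-missing")
  expect_identical(tab$test[tab$variable == "age"], "welch-t")
  expect_identical(tab$test[tab$variable == "sex"], "chi-squared")
  expect_identical(tab$test[tab$variable == "skewed"], "rank-sum")
  expect_false("all_na" %in% tab$variable)
  # welch statistic agrees with t.test on the same data
  ref <- t.test(covs$age[covs$group == 1], covs$age[covs$group == 0])
  expect_equal(tab$statistic[tab$variable == "age"],
               round(unname(ref$statistic), 2))
  # chi-squared Z matches the signed root of the chi-square statistic
  chi <- suppressWarnings(chisq.test(table(covs$group, covs$sex),
                                     correct = FALSE))
  expect_equal(abs(tab$statistic[tab$variable == "sex"]),
               round(sqrt(unname(chi$statistic)), 2))
})
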