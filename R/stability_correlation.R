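#' Feature-selection stability across outer loops
#'
#' Counts how often each feature appears in the per-loop selected sets;
#' features selected strictly more than `threshold` times are declared
#' stable. With the default 100-loop evaluation the conventional threshold
#' is 80; when `threshold` is `NULL` it defaults to 80% of the completed
#' loops, which keeps the same proportion in scaled-down runs.
#'
#' @param loops A [run_loops()] result.
#' @param threshold Count threshold (strict `>`); `NULL` for 0.8 x
#'   completed loops.
#' @param ft Optional [assemble_features()] table used to attach the group
#'   difference direction (sign of group-1 mean minus group-0 mean) and the
#'   mean LASSO weight per feature.
#' @return Object of class `stability_report`: data.frame `counts`
#'   (feature, count, mean_weight, direction), `stable` (character),
#'   `threshold`, `n_completed`.
#' @export
feature_stability <- function(loops, threshold = NULL, ft = NULL) {
  stopifnot(inherits(loops, "loop_results"))
  done <- setdiff(seq_along(loops$loops), loops$skipped)
  if (length(done) == 0) stop("no completed loops", call. = FALSE)
  if (is.null(threshold)) threshold <- 0.8 * length(done)
  sel_sets <- lapply(loops$loops[done], `[[`, "selected")
  all_feats <- sort(unique(unlist(sel_sets)))
  counts <- vapply(all_feats, function(f)
    sum(vapply(sel_sets, function(s) f %in% s, logical(1))), integer(1))
  weights <- vapply(all_feats, function(f) {
    w <- vapply(loops$loops[done], function(l) {
      b <- l$trace$lasso$beta
      if (!is.null(b) && f %in% names(b)) b[[f]] else NA_real_
    }, numeric(1))
    mean(w, na.rm = TRUE)
  }, numeric(1))
  direction <- rep(NA_integer_, length(all_feats))
  if (!is.null(ft)) {
    g1 <- ft$groups == 1
    direction <- vapply(all_feats, function(f) {
      as.integer(sign(mean(ft$x[g1, f]) - mean(ft$x[!g1, f])))
    }, integer(1))
  }
  tab <- data.frame(feature = all_feats, count = counts,
                    mean_weight = weights, direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[order(-tab$count, tab$feature), ]
  structure(list(counts = tab,
                 stable = tab$feature[tab$count > threshold],
                 threshold = threshold,
                 n_completed = length(done)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "stability_report: %d stable features (count > %.0f of %d loops)\n",
    length(x$stable), x$threshold, x$n_completed))
  print(utils::head(x$counts, 10), row.names = FALSE)
  invisible(x)
}

#' Partial Pearson correlation with covariates
#'
#' Correlates the residuals of `x` and `y` after least-squares projection
#' onto the covariates plus an intercept; p-value from the t distribution
#' with n - k - 2 degrees of freedom (k = number of non-constant
#' covariates). Constant covariate columns carry no information beyond the
#' intercept and are dropped; any remaining rank deficiency is an error
#' naming the collinear columns.
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric matrix or data.frame (may be `NULL` or have
#'   zero columns, giving the plain Pearson correlation).
#' @return List with `r`, `p`, `df`, `n`, `k`.
#' @export
partial_pearson <- function(x, y, covariates = NULL) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  Z <- if (is.null(covariates)) matrix(nrow = n, ncol = 0) else {
    as.matrix(covariates)
  }
  stopifnot(nrow(Z) == n)
  const <- apply(Z, 2, function(c) stats::sd(c) == 0)
  Z <- Z[, !const, drop = FALSE]
  k <- ncol(Z)
  if (n <= k + 2) stop("need n > number of covariates + 2", call. = FALSE)
  M <- cbind(`(Intercept)` = 1, Z)
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    bad <- colnames(M)[qrM$pivot[seq(qrM$rank + 1, ncol(M))]]
    stop("rank-deficient covariates: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rx <- stats::residuals(stats::lm.fit(M, x))
  ry <- stats::residuals(stats::lm.fit(M, y))
  r <- stats::cor(rx, ry)
  df <- n - k - 2
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  list(r = r, p = p, df = df, n = n, k = k)
}

#' Correlate stable features with clinical scores (group 1 only)
#'
#' Partial Pearson correlation of every stable feature against every
#' available clinical score within group-1 subjects, controlling for the
#' covariate columns, with Bonferroni correction over the number of tests
#' actually performed.
#'
#' @param ft A [assemble_features()] table with group labels.
#' @param features Character vector of feature names (e.g. the `stable` set
#'   of a [feature_stability()] report).
#' @param covariates Data.frame of per-subject covariates aligned with the
#'   feature table rows; must contain the score columns.
#' @param scores Clinical score column names to test (missing ones are
#'   skipped with a message).
#' @param covariate_cols Column names used as nuisance covariates.
#' @param alpha Familywise level before Bonferroni division.
#' @param n_tests Bonferroni divisor; defaults to the number of tests
#'   performed.
#' @return data.frame with feature, score, r, p, p_threshold, significant.
#' @export
correlate_clinical <- function(ft, features, covariates,
                               scores = c("trs_ab", "trs_c", "tetras"),
                               covariate_cols = c("age", "sex", "education",
                                                  "fd_power", "hdrs17",
                                                  "hars14", "mmse"),
                               alpha = 0.05, n_tests = NULL) {
  stopifnot(inherits(ft, "feature_table"), !is.null(ft$groups))
  features <- intersect(features, colnames(ft$x))
  scores_present <- intersect(scores, names(covariates))
  if (length(scores_present) < length(scores)) {
    message("skipping missing score column(s): ",
            paste(setdiff(scores, scores_present), collapse = ", "))
  }
  g1 <- which(ft$groups == 1)
  rows <- list()
  for (f in features) {
    for (s in scores_present) {
      ok <- g1[!is.na(covariates[[s]][g1])]
      if (length(ok) < length(covariate_cols) + 4) next
      pc <- partial_pearson(ft$x[ok, f], covariates[[s]][ok],
                            covariates[ok, covariate_cols, drop = FALSE])
      rows[[length(rows) + 1]] <- data.frame(feature = f, score = s,
                                             r = pc$r, p = pc$p,
                                             stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else {
    data.frame(feature = character(0), score = character(0),
               r = numeric(0), p = numeric(0))
  }
  if (is.null(n_tests)) n_tests <- max(1L, nrow(out))
  out$p_threshold <- alpha / n_tests
  out$significant <- out$p < out$p_threshold
  out
}

#' Welch t statistic from group summaries
#'
#' Unequal-variance two-sample t computed directly from per-group mean,
#' standard deviation and size, with Welch-Satterthwaite degrees of
#' freedom — usable when only summary statistics are published.
#'
#' @param mean1,sd1,n1 Group-1 summaries.
#' @param mean2,sd2,n2 Group-2 summaries.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  tval <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Demographic / clinical comparison table
#'
#' For each requested variable: continuous variables pass a
#' Kolmogorov-Smirnov normality gate (per group, at 0.05) and are compared
#' by Welch two-sample t-test when normal in both groups, otherwise by
#' Mann-Whitney rank-sum; binary variables are compared by chi-squared
#' without continuity correction, reported as a signed Z
#' (`sign(p1 - p2) * sqrt(chi2)`).
#'
#' @param covariates Data.frame with a 0/1 `group` column.
#' @param variables Variable names to compare; defaults to all columns
#'   except `subject` and `group`. Variables that are entirely missing in
#'   either group are skipped with a message.
#' @return data.frame: variable, group1 and group0 summaries
#'   ("mean ± sd" or counts), test, statistic (2 decimals), p.
#' @export
demographic_table <- function(covariates, variables = NULL) {
  stopifnot("group" %in% names(covariates),
            all(covariates$group %in% c(0, 1)))
  if (is.null(variables)) {
    variables <- setdiff(names(covariates), c("subject", "group"))
  }
  g1 <- covariates$group == 1
  rows <- list()
  for (v in variables) {
    x1 <- covariates[[v]][g1]
    x0 <- covariates[[v]][!g1]
    x1 <- x1[!is.na(x1)]; x0 <- x0[!is.na(x0)]
    if (length(x1) == 0 || length(x0) == 0) {
      message("skipping all-missing variable: ", v)
      next
    }
    is_binary <- all(c(x1, x0) %in% c(0, 1))
    if (is_binary) {
      tab <- rbind(c(sum(x1 == 1), sum(x1 == 0)),
                   c(sum(x0 == 1), sum(x0 == 0)))
      chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      z <- sign(mean(x1) - mean(x0)) * sqrt(chi$statistic)
      rows[[v]] <- data.frame(
        variable = v,
        group1 = sprintf("%d:%d", sum(x1 == 1), sum(x1 == 0)),
        group0 = sprintf("%d:%d", sum(x0 == 1), sum(x0 == 0)),
        test = "chi-squared",
        statistic = round(as.numeric(z), 2),
        p = as.numeric(chi$p.value))
    } else {
      normal <- ks_normal(x1) && ks_normal(x0)
      if (normal) {
        tt <- stats::t.test(x1, x0, var.equal = FALSE)
        stat <- tt$statistic; pv <- tt$p.value; test <- "welch-t"
      } else {
        wt <- suppressWarnings(stats::wilcox.test(x1, x0))
        stat <- stats::qnorm(wt$p.value / 2) *
          -sign(stats::median(x1) - stats::median(x0))
        pv <- wt$p.value; test <- "rank-sum"
      }
      rows[[v]] <- data.frame(
        variable = v,
        group1 = sprintf("%.2f ± %.2f", mean(x1), stats::sd(x1)),
        group0 = sprintf("%.2f ± %.2f", mean(x0), stats::sd(x0)),
        test = test,
        statistic = round(as.numeric(stat), 2),
        p = pv)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# KS normality gate at 0.05 on standardized values (returns TRUE when the
# sample is too small or degenerate to reject)
ks_normal <- function(x, level = 0.05) {
  if (length(unique(x)) < 3 || stats::sd(x) == 0) return(FALSE)
  p <- suppressWarnings(
    stats::ks.test((x - mean(x)) / stats::sd(x), "pnorm")$p.value)
  p > level
}
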