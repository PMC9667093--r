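#' Specify a classifier and its tuning grid
#'
#' Supported kinds: `"svm"` (support vector machine; grid over kernel,
#' penalty C and radial kernel width gamma), `"lr"` (L1-regularized
#' logistic regression; grid over inverse-penalty values Cs), `"rf"`
#' (random forest; grid over the number of base estimators), `"gnb"`
#' (Gaussian naive Bayes; no tunables). Hyperparameters are chosen by
#' exhaustive grid search maximizing mean stratified k-fold
#' cross-validation accuracy, ties broken toward the smaller-capacity
#' setting (linear before radial kernel, smaller C/Cs, fewer estimators).
#'
#' @param kind One of `"svm"`, `"lr"`, `"rf"`, `"gnb"`.
#' @param grid Optional named list overriding the default grid
#'   (`C`, `gamma`, `kernel` for svm; `Cs` for lr; `ntree` for rf).
#' @param inner_folds Inner CV folds for grid search (default 10).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(kind = c("svm", "lr", "rf", "gnb"), grid = NULL,
                       inner_folds = 10L) {
  kind <- match.arg(kind)
  default <- switch(kind,
    svm = list(kernel = c("linear", "radial"),
               C = c(0.01, 0.1, 1, 10, 100),
               gamma = 10^seq(-4, 1, length.out = 6)),
    lr = list(Cs = 10^seq(-3, 3, length.out = 10)),
    rf = list(ntree = c(100L, 200L, 500L)),
    gnb = list()
  )
  if (!is.null(grid)) default[names(grid)] <- grid
  if (kind != "gnb" && any(lengths(default) == 0)) {
    stop("tuning grid must be non-empty for kind ", kind, call. = FALSE)
  }
  structure(list(kind = kind, grid = default,
                 inner_folds = as.integer(inner_folds)),
            class = "model_spec")
}

#' Confusion-matrix performance metrics
#'
#' Positives are class 1. Accuracy = (TP+TN)/(TP+TN+FP+FN), sensitivity =
#' TP/(TP+FN), specificity = TN/(TN+FP), balanced accuracy =
#' (sensitivity + specificity)/2.
#'
#' @param y_true,y_pred 0/1 vectors.
#' @return Named list with the four metrics and the confusion counts.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0,
            all(y_true %in% c(0, 1)), all(y_pred %in% c(0, 1)))
  if (all(y_true == 1) || all(y_true == 0)) {
    stop("sensitivity/specificity undefined: one class absent from y_true",
         call. = FALSE)
  }
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  list(accuracy = (tp + tn) / length(y_true),
       sensitivity = sens, specificity = spec,
       balanced_accuracy = (sens + spec) / 2,
       tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Rank-based ROC AUC
#'
#' Probability that a random positive outscores a random negative, ties
#' counted one half (equals the trapezoidal area under the ROC curve).
#'
#' @param scores Numeric classifier scores, larger = more class-1.
#' @param y_true 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, y_true) {
  stopifnot(length(scores) == length(y_true), all(y_true %in% c(0, 1)))
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Grid-search tuning and final fit of one classifier
#'
#' Exhaustive search over the model's grid; the selection criterion is mean
#' accuracy over stratified inner cross-validation folds; ties go to the
#' first grid row in capacity order. The winning configuration is refit on
#' all training rows.
#'
#' @param spec A [model_spec()].
#' @param x Numeric training matrix (standardized features).
#' @param y 0/1 labels.
#' @param seed Integer seed (fold assignment).
#' @return List with `fit` (an internal predictor closure), `params`
#'   (chosen hyperparameters), `cv_accuracy`.
#' @export
tune_and_fit <- function(spec, x, y, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"), ncol(x) >= 1)
  y <- as.integer(y)
  k <- min(spec$inner_folds, min(table(y)))
  if (k < 2) stop("need at least 2 subjects per class for inner CV",
                  call. = FALSE)
  folds <- stratified_folds(y, k, derive_seed(seed, 11))
  rows <- grid_rows(spec)
  acc <- numeric(length(rows))
  for (f in seq_len(k)) {
    tr <- folds != f
    preds <- fit_predict_grid(spec, rows, x[tr, , drop = FALSE], y[tr],
                              x[!tr, , drop = FALSE], seed)
    for (i in seq_along(rows)) {
      acc[i] <- acc[i] + mean(preds[[i]]$class == y[!tr]) / k
    }
  }
  best <- which.max(acc)  # first max = smallest capacity by construction
  final <- fit_one(spec, rows[[best]], x, y, seed)
  list(fit = final, params = rows[[best]], cv_accuracy = acc[best])
}

# grid rows enumerated in increasing-capacity order
grid_rows <- function(spec) {
  g <- spec$grid
  switch(spec$kind,
    svm = {
      rows <- list()
      for (kern in intersect(c("linear", "radial"), g$kernel)) {
        for (C in sort(g$C)) {
          if (kern == "linear") {
            rows[[length(rows) + 1]] <- list(kernel = "linear", C = C)
          } else {
            for (gam in sort(g$gamma)) {
              rows[[length(rows) + 1]] <- list(kernel = "radial", C = C,
                                               gamma = gam)
            }
          }
        }
      }
      rows
    },
    lr = lapply(sort(g$Cs), function(C) list(Cs = C)),
    rf = lapply(sort(g$ntree), function(nt) list(ntree = nt)),
    gnb = list(list())
  )
}

# probability predictions robust to early-terminated glmnet paths: requested
# lambdas are clamped to the fitted range (an unconverged saturated fit at
# tiny lambda returns only the larger lambdas), and single-lambda fits avoid
# the s= interpolation path entirely
predict_binomial_prob <- function(fit, nx, s) {
  lams <- fit$lambda
  if (length(lams) == 1) {
    p <- stats::predict(fit, nx, type = "response")[, 1]
    return(matrix(p, nrow(nx), length(s)))
  }
  s2 <- pmin(pmax(s, min(lams)), max(lams))
  stats::predict(fit, nx, s = s2, type = "response")
}

# fit every grid row once per fold; lr exploits the glmnet lambda path so
# all Cs values come from a single fit
fit_predict_grid <- function(spec, rows, xtr, ytr, xte, seed) {
  if (spec$kind == "lr") {
    lam <- lr_lambdas(vapply(rows, `[[`, numeric(1), "Cs"), nrow(xtr))
    fit <- glmnet_binomial(xtr, ytr, lam)
    prob <- predict_binomial_prob(fit, pad_single_column(xte), lam)
    lapply(seq_along(rows), function(i) {
      list(class = as.integer(prob[, i] > 0.5), score = prob[, i])
    })
  } else {
    lapply(rows, function(r) {
      m <- fit_one(spec, r, xtr, ytr, seed)
      list(class = m$predict_class(xte), score = m$predict_score(xte))
    })
  }
}

# sklearn-style inverse penalty: lambda = 1/(Cs * n)
lr_lambdas <- function(Cs, n) 1 / (sort(Cs) * n)

glmnet_binomial <- function(x, y, lambda) {
  glmnet::glmnet(pad_single_column(x), y, family = "binomial", alpha = 1,
                 lambda = sort(lambda, decreasing = TRUE),
                 standardize = FALSE)
}

# returns a fitted predictor with class/score closures; score is the
# decision margin (svm) or the class-1 probability (lr, rf, gnb)
fit_one <- function(spec, params, x, y, seed) {
  yf <- factor(y, levels = c(0, 1))
  switch(spec$kind,
    svm = {
      fit <- e1071::svm(x, yf, kernel = params$kernel, cost = params$C,
                        gamma = if (is.null(params$gamma)) 1 / ncol(x)
                                else params$gamma,
                        scale = FALSE)
      list(predict_class = function(nx)
             as.integer(as.character(stats::predict(fit, nx))),
           predict_score = function(nx) {
             dv <- attr(stats::predict(fit, nx, decision.values = TRUE),
                        "decision.values")
             # column named "a/b": positive margin favours class a
             orient <- if (startsWith(colnames(dv)[1], "1")) 1 else -1
             orient * dv[, 1]
           })
    },
    lr = {
      lam <- 1 / (params$Cs * nrow(x))
      fit <- glmnet_binomial(x, y, c(lam * 2, lam))
      list(predict_class = function(nx)
             as.integer(predict_binomial_prob(fit, pad_single_column(nx),
                                              lam)[, 1] > 0.5),
           predict_score = function(nx)
             predict_binomial_prob(fit, pad_single_column(nx), lam)[, 1])
    },
    rf = {
      fit <- with_seed(derive_seed(seed, 23),
        randomForest::randomForest(x, yf, ntree = params$ntree))
      list(predict_class = function(nx)
             as.integer(as.character(stats::predict(fit, nx))),
           predict_score = function(nx)
             stats::predict(fit, nx, type = "prob")[, "1"])
    },
    gnb = {
      fit <- e1071::naiveBayes(x, yf)
      list(predict_class = function(nx)
             as.integer(as.character(stats::predict(fit, nx))),
           predict_score = function(nx)
             stats::predict(fit, nx, type = "raw")[, "1"])
    }
  )
}

# run selection + tuning + test scoring for one split; the selection
# cascade and all tuning see training rows only
evaluate_split <- function(ft, split, models, seed,
                           alpha = 0.01, cutoff = 0.7, cv_folds = 5) {
  trace <- select_features(ft, split$train, alpha = alpha, cutoff = cutoff,
                           cv_folds = cv_folds, seed = derive_seed(seed, 5))
  gtr <- ft$groups[split$train]
  gte <- ft$groups[split$test]
  out <- list(split_seed = split$seed, selected = trace$selected,
              trace = trace, models = list(),
              empty_selection = length(trace$selected) == 0)
  if (out$empty_selection) {
    # chance-level fallback: majority training class, constant score
    maj <- as.integer(mean(gtr) >= 0.5)
    pred <- rep(maj, length(gte))
    cm <- confusion_metrics(gte, pred)
    for (m in names(models)) {
      out$models[[m]] <- c(cm, list(auc = 0.5, params = list(),
                                    cv_accuracy = NA_real_))
    }
    return(out)
  }
  xtr <- apply_scaler(trace$scaler,
                      ft$x[split$train, trace$spearman$kept, drop = FALSE])
  xte <- apply_scaler(trace$scaler,
                      ft$x[split$test, trace$spearman$kept, drop = FALSE])
  xtr <- xtr[, trace$selected, drop = FALSE]
  xte <- xte[, trace$selected, drop = FALSE]
  for (m in names(models)) {
    tuned <- tune_and_fit(models[[m]], xtr, gtr, seed = derive_seed(seed, 7))
    pred <- tuned$fit$predict_class(xte)
    score <- tuned$fit$predict_score(xte)
    cm <- confusion_metrics(gte, pred)
    out$models[[m]] <- c(cm, list(auc = roc_auc(score, gte),
                                  params = tuned$params,
                                  cv_accuracy = tuned$cv_accuracy))
  }
  out
}

#' Repeated stratified train/test evaluation (outer loops)
#'
#' Loop k draws a stratified split with seed `master_seed + k`, runs the
#' full selection cascade on the training split, tunes and fits every
#' requested classifier, and scores the held-out split. Loops whose
#' selection cascade returns no feature are skipped and logged; the summary
#' averages over completed loops.
#'
#' @param ft A [assemble_features()] table with group labels.
#' @param models Named list of [model_spec()]s (default: all four kinds).
#' @param n_loops Number of outer loops (default 100).
#' @param master_seed Integer master seed.
#' @param test_frac Held-out fraction per loop.
#' @param alpha,cutoff,cv_folds Selection-cascade parameters.
#' @return Object of class `loop_results`: list with `loops` (per-loop
#'   records), `summary` (per-model mean and sd of accuracy, balanced
#'   accuracy, sensitivity, specificity, auc), `skipped` (loop ids),
#'   `n_completed`.
#' @export
run_loops <- function(ft, models = default_models(), n_loops = 100L,
                      master_seed = 1L, test_frac = 0.30,
                      alpha = 0.01, cutoff = 0.7, cv_folds = 5) {
  stopifnot(inherits(ft, "feature_table"), n_loops >= 1)
  loops <- vector("list", n_loops)
  for (k in seq_len(n_loops)) {
    split <- stratified_split(ft$groups, test_frac, seed = master_seed + k)
    # empty selections surface through the skip log, not per-loop warnings
    loops[[k]] <- suppressWarnings(
      evaluate_split(ft, split, models, seed = master_seed + k,
                     alpha = alpha, cutoff = cutoff, cv_folds = cv_folds))
    loops[[k]]$loop <- k
  }
  skipped <- which(vapply(loops, `[[`, logical(1), "empty_selection"))
  done <- setdiff(seq_len(n_loops), skipped)
  metric_names <- c("accuracy", "balanced_accuracy", "sensitivity",
                    "specificity", "auc")
  summary <- lapply(names(models), function(m) {
    vals <- sapply(metric_names, function(s)
      vapply(loops[done], function(l) l$models[[m]][[s]], numeric(1)))
    vals <- matrix(vals, nrow = length(done),
                   dimnames = list(NULL, metric_names))
    list(mean = colMeans(vals), sd = apply(vals, 2, stats::sd))
  })
  names(summary) <- names(models)
  structure(list(loops = loops, summary = summary, skipped = skipped,
                 n_completed = length(done), models = names(models),
                 master_seed = as.integer(master_seed)),
            class = "loop_results")
}

#' Default classifier set
#'
#' @param inner_folds Inner CV folds for every model.
#' @return Named list of [model_spec()]s for svm, lr, rf and gnb.
#' @export
default_models <- function(inner_folds = 10L) {
  list(svm = model_spec("svm", inner_folds = inner_folds),
       lr = model_spec("lr", inner_folds = inner_folds),
       rf = model_spec("rf", inner_folds = inner_folds),
       gnb = model_spec("gnb", inner_folds = inner_folds))
}

#' @export
print.loop_results <- function(x, ...) {
  cat(sprintf("loop_results: %d completed loops (%d skipped)\n",
              x$n_completed, length(x$skipped)))
  for (m in x$models) {
    s <- x$summary[[m]]
    cat(sprintf("  %-4s accuracy %.3f +/- %.3f, balanced %.3f, AUC %.3f\n",
                m, s$mean["accuracy"], s$sd["accuracy"],
                s$mean["balanced_accuracy"], s$mean["auc"]))
  }
  invisible(x)
}

#' Permutation test of classifier performance
#'
#' Shuffles the class labels `n_perm` times; each permutation reruns the
#' complete pipeline (selection cascade, tuning, held-out scoring) on one
#' stratified split. p = (#\{permuted >= actual\} + 1) / (n_perm + 1),
#' separately for accuracy and AUC. Permutations whose selection cascade is
#' empty are kept as chance-level results so the null distribution is not
#' censored.
#'
#' @param ft A [assemble_features()] table with group labels.
#' @param model A [model_spec()] (default L1 logistic regression).
#' @param n_perm Number of permutations (default 1000; scale down for desk
#'   runs).
#' @param master_seed Integer seed.
#' @param test_frac,alpha,cutoff,cv_folds Pipeline parameters.
#' @return Object of class `permutation_result`: `actual` (accuracy, auc),
#'   `perm_accuracy`, `perm_auc`, `p_accuracy`, `p_auc`.
#' @export
permutation_test <- function(ft, model = model_spec("lr"), n_perm = 1000L,
                             master_seed = 1L, test_frac = 0.30,
                             alpha = 0.01, cutoff = 0.7, cv_folds = 5) {
  stopifnot(inherits(ft, "feature_table"), n_perm >= 1)
  models <- list(m = model)
  eval_with_labels <- function(groups, seed) {
    ft2 <- ft
    ft2$groups <- groups
    split <- stratified_split(groups, test_frac, seed = seed)
    res <- suppressWarnings(
      evaluate_split(ft2, split, models, seed = seed,
                     alpha = alpha, cutoff = cutoff, cv_folds = cv_folds))
    c(accuracy = res$models$m$accuracy, auc = res$models$m$auc)
  }
  actual <- eval_with_labels(ft$groups, derive_seed(master_seed, 0))
  perm <- matrix(NA_real_, n_perm, 2, dimnames = list(NULL, c("accuracy", "auc")))
  for (b in seq_len(n_perm)) {
    g <- with_seed(derive_seed(master_seed, b, 1), sample(ft$groups))
    perm[b, ] <- eval_with_labels(g, derive_seed(master_seed, b, 2))
  }
  structure(list(actual = actual,
                 perm_accuracy = perm[, "accuracy"],
                 perm_auc = perm[, "auc"],
                 p_accuracy = (sum(perm[, "accuracy"] >= actual["accuracy"]) + 1) /
                   (n_perm + 1),
                 p_auc = (sum(perm[, "auc"] >= actual["auc"]) + 1) /
                   (n_perm + 1),
                 n_perm = as.integer(n_perm)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation_result: actual accuracy %.3f (p = %.4f), AUC %.3f (p = %.4f), %d permutations\n",
    x$actual["accuracy"], x$p_accuracy, x$actual["auc"], x$p_auc, x$n_perm))
  invisible(x)
}
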