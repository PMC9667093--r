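#' Area under the curve of a metric across the sparsity grid
#'
#' Trapezoidal integral of per-threshold metric values over the sparsity
#' axis — the threshold-free summary used as an additional feature per
#' metric.
#'
#' @param values Numeric vector, one finite value per grid point.
#' @param grid A [threshold_grid()].
#' @return Scalar integral.
#' @export
auc_over_thresholds <- function(values, grid = threshold_grid()) {
  S <- as.numeric(grid)
  if (length(values) != length(S) || any(!is.finite(values))) {
    stop("need one finite metric value per grid point", call. = FALSE)
  }
  sum((values[-1] + values[-length(values)]) / 2 * diff(S))
}

#' Assemble the subjects-by-features table from a metric panel
#'
#' Columns follow a canonical scheme and order: for each global metric the
#' per-threshold values (`Eglobal_thr0.20`, ...) then its AUC (`aEglobal`);
#' then for each node, for each nodal metric, per-threshold values
#' (`DC_thr0.35_node042`) then AUC (`aDC_node042`). For an atlas of n nodes
#' and a grid of L thresholds the column count is `5 n (L+1) + 7 (L+1)` —
#' 8,877 for 160 nodes and the default 10-level grid.
#'
#' @param panel A [compute_metric_panel()] result.
#' @param groups Optional 0/1 group labels per subject (named or in panel
#'   subject order).
#' @return Object of class `feature_table`: list with `x` (numeric matrix,
#'   subjects x features), `groups`, `subjects`, `grid`.
#' @export
assemble_features <- function(panel, groups = NULL) {
  stopifnot(inherits(panel, "metric_panel"))
  glob <- panel$global
  noda <- panel$nodal
  if (anyNA(glob) || anyNA(noda)) {
    g_na <- which(is.na(glob), arr.ind = TRUE)
    n_na <- which(is.na(noda), arr.ind = TRUE)
    cell <- if (nrow(g_na) > 0) {
      paste(dimnames(glob)[[1]][g_na[1, 1]], dimnames(glob)[[2]][g_na[1, 2]],
            dimnames(glob)[[3]][g_na[1, 3]])
    } else {
      paste(dimnames(noda)[[1]][n_na[1, 1]], dimnames(noda)[[2]][n_na[1, 2]],
            dimnames(noda)[[3]][n_na[1, 3]])
    }
    stop("missing metric cell: ", cell, call. = FALSE)
  }
  n_sub <- dim(glob)[1]
  n_thr <- dim(glob)[2]
  n_nodes <- dim(noda)[4]
  thr_tag <- paste0("_thr", dimnames(glob)[[2]])

  blocks <- vector("list", length(global_metric_names) +
                     n_nodes * length(nodal_metric_names))
  b <- 0L
  for (m in global_metric_names) {
    vals <- glob[, , m, drop = FALSE]
    dim(vals) <- c(n_sub, n_thr)
    auc <- apply(vals, 1, auc_over_thresholds, grid = panel$grid)
    block <- cbind(vals, auc)
    colnames(block) <- c(paste0(m, thr_tag), paste0("a", m))
    b <- b + 1L
    blocks[[b]] <- block
  }
  node_tag <- sprintf("_node%03d", seq_len(n_nodes))
  for (v in seq_len(n_nodes)) {
    for (m in nodal_metric_names) {
      vals <- noda[, , m, v, drop = FALSE]
      dim(vals) <- c(n_sub, n_thr)
      auc <- apply(vals, 1, auc_over_thresholds, grid = panel$grid)
      block <- cbind(vals, auc)
      colnames(block) <- c(paste0(m, thr_tag, node_tag[v]),
                           paste0("a", m, node_tag[v]))
      b <- b + 1L
      blocks[[b]] <- block
    }
  }
  x <- do.call(cbind, blocks)
  rownames(x) <- panel$subjects
  if (!is.null(groups)) {
    if (!is.null(names(groups))) groups <- groups[panel$subjects]
    stopifnot(length(groups) == n_sub, all(groups %in% c(0, 1)))
    groups <- as.integer(groups)
  }
  structure(list(x = x, groups = groups, subjects = panel$subjects,
                 grid = panel$grid, node_labels = panel$node_labels),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d subjects x %d features\n",
              nrow(x$x), ncol(x$x)))
  invisible(x)
}

#' Stratified train/test split
#'
#' Samples, within each group separately and without replacement,
#' `round-half-up(group size * test_frac)` subjects into the test set.
#'
#' @param groups 0/1 vector of group labels.
#' @param test_frac Test fraction (default 0.30).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`, plus `seed`
#'   and `test_frac`.
#' @export
stratified_split <- function(groups, test_frac = 0.30, seed = 1L) {
  stopifnot(all(groups %in% c(0, 1)), test_frac > 0, test_frac < 1)
  if (min(table(groups)) < 2) {
    stop("each group needs at least 2 subjects for a stratified split",
         call. = FALSE)
  }
  test <- with_seed(seed, {
    unlist(lapply(c(0, 1), function(g) {
      idx <- which(groups == g)
      k <- as.integer(round_half_up(length(idx) * test_frac))
      if (k == 0 || k == length(idx)) {
        stop("test fraction leaves an empty train or test group",
             call. = FALSE)
      }
      sort(sample(idx, k))
    }), use.names = FALSE)
  })
  test <- sort(test)
  list(train = setdiff(seq_along(groups), test), test = test,
       seed = as.integer(seed), test_frac = test_frac)
}

#' Mann-Whitney U screen over feature columns
#'
#' Two-sided rank-sum test per feature; features with p below `alpha`
#' survive. Uses the tie-corrected normal approximation (no continuity
#' correction), or exact enumeration when both groups have at most 8
#' subjects and the column has no ties. Constant columns get p = 1.
#'
#' @param x Numeric matrix (training rows only) subjects x features.
#' @param groups 0/1 labels for the rows of `x`.
#' @param alpha Survival threshold (default 0.01, strict `<`).
#' @return List with `p` (named numeric) and `survivors` (logical mask).
#' @export
mannwhitney_screen <- function(x, groups, alpha = 0.01) {
  stopifnot(nrow(x) == length(groups), all(groups %in% c(0, 1)))
  g1 <- groups == 1
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2) stop("both groups need >= 2 training subjects",
                             call. = FALSE)
  n <- n1 + n2
  p <- numeric(ncol(x))
  exact_scale <- n1 <= 8 && n2 <= 8
  rk <- col_midranks(x)
  ranks <- rk$ranks
  tie_terms <- rk$tie_terms
  U <- colSums(ranks[g1, , drop = FALSE]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_terms / (n * (n - 1)))
  for (j in seq_len(ncol(x))) {
    if (sigma2[j] <= 0) {
      p[j] <- 1
    } else if (exact_scale && tie_terms[j] == 0) {
      p[j] <- stats::wilcox.test(x[g1, j], x[!g1, j], exact = TRUE)$p.value
    } else {
      z <- (U[j] - mu) / sqrt(sigma2[j])
      p[j] <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  names(p) <- colnames(x)
  list(p = p, survivors = p < alpha)
}

# midranks (average ties) of every column at once: one global sort, run
# detection within columns, and the per-column tie term sum(t^3 - t)
col_midranks <- function(x) {
  n <- nrow(x); pn <- ncol(x)
  np <- n * pn
  cid <- rep(seq_len(pn), each = n)
  o <- order(cid, as.vector(x))
  v <- as.vector(x)[o]
  pos <- rep(seq_len(n), pn)
  newrun <- (pos == 1) | c(TRUE, v[-1] != v[-np])
  first <- which(newrun)
  last <- c(first[-1] - 1L, np)
  len <- last - first + 1L
  mid <- (pos[first] + pos[last]) / 2
  mr <- mid[rep.int(seq_along(first), len)]
  ranks <- matrix(0, n, pn)
  ranks[o] <- mr
  agg <- rowsum(as.numeric(len)^3 - len, cid[first])
  tie_terms <- numeric(pn)
  tie_terms[as.integer(rownames(agg))] <- agg[, 1]
  list(ranks = ranks, tie_terms = tie_terms)
}

#' Greedy Spearman collinearity pruning
#'
#' Iterates surviving features in canonical column order; a later feature is
#' removed when its absolute training-set Spearman correlation with any
#' already-retained feature exceeds `cutoff`. The removal log records each
#' removed feature, the retained partner that triggered removal, and rho.
#'
#' @param x Numeric matrix (training rows only).
#' @param survivors Logical mask or character/integer selection of columns
#'   entering the pruning, in canonical order.
#' @param cutoff Absolute Spearman threshold (default 0.7, strict `>`).
#' @return List with `kept` (character), `removed` (data.frame feature,
#'   partner, rho).
#' @export
spearman_prune <- function(x, survivors, cutoff = 0.7) {
  cols <- if (is.logical(survivors)) which(survivors) else {
    if (is.character(survivors)) match(survivors, colnames(x)) else survivors
  }
  cols <- sort(cols)
  if (length(cols) == 0) {
    return(list(kept = character(0),
                removed = data.frame(feature = character(0),
                                     partner = character(0),
                                     rho = numeric(0))))
  }
  xs <- x[, cols, drop = FALSE]
  C <- stats::cor(col_midranks(xs)$ranks)  # Pearson of ranks = Spearman
  keep <- integer(0)
  rem_f <- rem_p <- character(0)
  rem_r <- numeric(0)
  for (j in seq_along(cols)) {
    if (length(keep) > 0) {
      rho <- C[j, keep]
      hit <- which(abs(rho) > cutoff)
      if (length(hit) > 0) {
        rem_f <- c(rem_f, colnames(xs)[j])
        rem_p <- c(rem_p, colnames(xs)[keep[hit[1]]])
        rem_r <- c(rem_r, rho[hit[1]])
        next
      }
    }
    keep <- c(keep, j)
  }
  list(kept = colnames(xs)[keep],
       removed = data.frame(feature = rem_f, partner = rem_p, rho = rem_r,
                            stringsAsFactors = FALSE))
}

#' Fit / apply a column standardizer
#'
#' `feature_scaler` computes training means and standard deviations;
#' `apply_scaler` centres and scales any table with those training
#' parameters.
#'
#' @param x Numeric training matrix.
#' @return `feature_scaler`: list with `mean`, `sd` (named).
#' @export
feature_scaler <- function(x) {
  m <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  if (any(s == 0)) {
    stop("zero-variance feature(s): ",
         paste(colnames(x)[s == 0], collapse = ", "), call. = FALSE)
  }
  structure(list(mean = m, sd = s), class = "feature_scaler")
}

#' @rdname feature_scaler
#' @param scaler A `feature_scaler`.
#' @param newx Matrix with the same columns as the training table.
#' @export
apply_scaler <- function(scaler, newx) {
  stopifnot(inherits(scaler, "feature_scaler"),
            identical(colnames(newx), names(scaler$mean)))
  sweep(sweep(newx, 2, scaler$mean), 2, scaler$sd, "/")
}

#' Squared-error LASSO path
#'
#' Minimizes `(1/2n) * sum((y - b0 - X b)^2) + lambda * sum(|b|)` over a
#' decreasing lambda sequence. The `1/(2n)` scaling only reparameterizes
#' the residual-sum-of-squares + L1 loss; the regularization path is
#' identical. The solver follows the exact piecewise-linear solution path
#' (LARS-style homotopy on the stationarity system `G_A b_A = q_A -
#' lambda s_A`), evaluating it at the requested grid; if the active-set
#' system becomes numerically singular it falls back to covariance-form
#' cyclic coordinate descent with warm starts.
#'
#' @param x Numeric matrix (n x p).
#' @param y Numeric response.
#' @param lambda Decreasing penalty sequence.
#' @param tol Convergence tolerance of the coordinate-descent fallback.
#' @param max_sweeps Sweep cap of the coordinate-descent fallback.
#' @return List with `beta` (p x length(lambda)), `intercept`
#'   (length(lambda)), `lambda`.
#' @export
lasso_path <- function(x, y, lambda, tol = 1e-7, max_sweeps = 2000L) {
  lambda <- sort(lambda, decreasing = TRUE)
  xm <- colMeans(x)
  ym <- mean(y)
  xc <- sweep(x, 2, xm)
  yc <- y - ym
  n <- nrow(x)
  G <- crossprod(xc) / n
  q <- as.numeric(crossprod(xc, yc)) / n
  beta <- tryCatch(lasso_homotopy(G, q, lambda),
                   error = function(e)
                     lasso_cd(G, q, lambda, tol, max_sweeps))
  intercept <- ym - as.numeric(crossprod(beta, xm))
  list(beta = beta, intercept = intercept, lambda = lambda)
}

# exact homotopy: within an active set A with signs s, the solution is
# b_A(lambda) = u - lambda v with u = G_AA^-1 q_A, v = G_AA^-1 s_A; events
# are coefficient zero-crossings and inactive constraints |c_j| = lambda
lasso_homotopy <- function(G, q, grid) {
  p <- length(q)
  beta <- matrix(0, p, length(grid))
  lam0 <- max(abs(q))
  if (lam0 <= 0 || all(grid >= lam0)) return(beta)
  eps <- 1e-12
  j0 <- which.max(abs(q))
  A <- j0
  sA <- sign(q[j0])
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 4L * p + 100L) stop("homotopy did not terminate")
    GA <- G[A, A, drop = FALSE]
    u <- solve(GA, q[A])
    v <- solve(GA, sA)
    # zero-crossing events of active coefficients
    lz <- u / v
    lz[!is.finite(lz) | lz <= eps | lz >= lam0 - eps] <- NA
    # activation events of inactive constraints
    inact <- setdiff(seq_len(p), A)
    la <- rep(NA_real_, length(inact))
    if (length(inact) > 0) {
      gv <- G[inact, A, drop = FALSE]
      a0 <- as.numeric(q[inact] - gv %*% u)   # c_j(lambda) = a0 + lambda w
      w <- as.numeric(gv %*% v)
      for (sgn in c(1, -1)) {
        cand <- a0 / (sgn - w)
        ok <- is.finite(cand) & cand > eps & cand < lam0 - eps
        la[ok] <- pmax(la[ok], cand[ok], na.rm = TRUE)
      }
    }
    lstar <- suppressWarnings(max(c(lz, la), na.rm = TRUE))
    if (!is.finite(lstar)) lstar <- 0
    # evaluate this linear segment at grid points in (lstar, lam0)
    idx <- which(grid < lam0 - eps & grid >= lstar - eps)
    if (length(idx) > 0) {
      beta[A, idx] <- u - v %o% grid[idx]
    }
    if (lstar <= min(grid) || lstar <= 0) break
    zcross <- which(!is.na(lz) & abs(lz - lstar) <= eps * max(1, lstar))
    if (length(zcross) > 0) {
      A <- A[-zcross[1]]
      sA <- sA[-zcross[1]]
      if (length(A) == 0) stop("active set emptied")  # fallback handles this
    } else {
      hit <- which(!is.na(la) & abs(la - lstar) <= eps * max(1, lstar))[1]
      jnew <- inact[hit]
      A <- c(A, jnew)
      sA <- c(sA, sign(a0[hit] + lstar * w[hit]))
    }
    lam0 <- lstar
  }
  beta
}

# covariance-form cyclic coordinate descent with warm starts (fallback)
lasso_cd <- function(G, q, lambda, tol, max_sweeps) {
  p <- length(q)
  d <- diag(G)
  all_idx <- which(d > 0)
  beta <- matrix(0, p, length(lambda))
  b <- numeric(p)
  Gb <- numeric(p)  # maintained G %*% b, updated incrementally
  for (l in seq_along(lambda)) {
    lam <- lambda[l]
    for (sweep_i in seq_len(max_sweeps)) {
      delta <- 0
      for (j in all_idx) {
        r <- q[j] - Gb[j] + d[j] * b[j]
        a <- abs(r)
        bj <- if (a > lam) sign(r) * (a - lam) / d[j] else 0
        ch <- bj - b[j]
        if (ch != 0) {
          b[j] <- bj
          Gb <- Gb + G[, j] * ch
          if (abs(ch) > delta) delta <- abs(ch)
        }
      }
      if (delta < tol) break
    }
    beta[, l] <- b
  }
  beta
}

#' Squared-error LASSO selection with stratified cross-validated lambda
#'
#' Runs [lasso_path()] on the 0/1 labels. The lambda grid defaults to 50
#' log-spaced points from the smallest all-zero lambda down three decades;
#' the optimum minimizes mean squared error over stratified
#' cross-validation folds, and the selected set is the support of the
#' refit on the full training table.
#'
#' @param x Standardized numeric training matrix.
#' @param y 0/1 labels.
#' @param lambda_grid Optional decreasing lambda grid (in the `1/(2n)` RSS
#'   parameterization).
#' @param cv_folds Number of stratified folds (default 5).
#' @param seed Integer seed for fold assignment.
#' @return List with `lambda_grid`, `cv_mse`, `lambda_opt`, `beta` (named,
#'   full length), `intercept`, `selected` (names with nonzero beta).
#' @export
lasso_select <- function(x, y, lambda_grid = NULL, cv_folds = 5, seed = 1L) {
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  y <- as.numeric(y)
  n <- nrow(x)
  if (is.null(lambda_grid)) {
    lmax <- max(abs(crossprod(x, y - mean(y)))) / n
    if (lmax <= 0) lmax <- 1e-3
    lambda_grid <- exp(seq(log(lmax), log(lmax * 1e-3), length.out = 50))
  }
  if (length(lambda_grid) == 0) stop("empty lambda grid", call. = FALSE)
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  folds <- stratified_folds(y, cv_folds, seed)
  cv_mse <- matrix(NA_real_, cv_folds, length(lambda_grid))
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    fit <- lasso_path(x[tr, , drop = FALSE], y[tr], lambda_grid)
    pred <- x[!tr, , drop = FALSE] %*% fit$beta +
      rep(fit$intercept, each = sum(!tr))
    cv_mse[f, ] <- colMeans((pred - y[!tr])^2)
  }
  mean_mse <- colMeans(cv_mse)
  opt <- which.min(mean_mse)
  lambda_opt <- lambda_grid[opt]
  full <- lasso_path(x, y, lambda_grid)
  beta <- full$beta[, opt]
  names(beta) <- colnames(x)
  selected <- names(beta)[beta != 0]
  if (length(selected) == 0) {
    warning("LASSO selected no features at the optimal lambda")
  }
  list(lambda_grid = lambda_grid, cv_mse = mean_mse, lambda_opt = lambda_opt,
       beta = beta, intercept = full$intercept[opt], selected = selected)
}

# glmnet (the L1 logistic classifier) needs >= 2 columns; pad with a zero
# dummy that can never be selected
pad_single_column <- function(x) {
  if (ncol(x) >= 2) return(x)
  cbind(x, .zero_pad = 0)
}

# fold id per row, stratified by label, sizes as equal as possible
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (g in unique(y)) {
      idx <- which(y == g)
      if (length(idx) < k) {
        stop("fewer subjects than folds in one class", call. = FALSE)
      }
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Run the full feature-selection cascade on a training split
#'
#' Mann-Whitney screen (p < `alpha`), greedy Spearman pruning
#' (|rho| > `cutoff`), standardization fitted on training rows, then
#' squared-error LASSO with stratified cross-validated lambda. All
#' statistics are computed from training rows only.
#'
#' @param ft A [assemble_features()] table with group labels.
#' @param train Integer indices of training rows.
#' @param alpha Screen threshold.
#' @param cutoff Spearman pruning threshold.
#' @param cv_folds LASSO CV folds.
#' @param seed Integer seed.
#' @return Object of class `selection_trace`: the per-stage records plus
#'   `selected` feature names, the fitted `scaler`, and LASSO weights.
#' @export
select_features <- function(ft, train, alpha = 0.01, cutoff = 0.7,
                            cv_folds = 5, seed = 1L) {
  stopifnot(inherits(ft, "feature_table"), !is.null(ft$groups))
  xtr <- ft$x[train, , drop = FALSE]
  gtr <- ft$groups[train]
  screen <- mannwhitney_screen(xtr, gtr, alpha = alpha)
  if (!any(screen$survivors)) {
    return(structure(list(utest_p = screen$p, utest_survivors = character(0),
                          spearman = NULL, scaler = NULL, lasso = NULL,
                          selected = character(0)),
                     class = "selection_trace"))
  }
  prune <- spearman_prune(xtr, screen$survivors, cutoff = cutoff)
  scaler <- feature_scaler(xtr[, prune$kept, drop = FALSE])
  xs <- apply_scaler(scaler, xtr[, prune$kept, drop = FALSE])
  lasso <- lasso_select(xs, gtr, cv_folds = cv_folds, seed = seed)
  structure(list(utest_p = screen$p,
                 utest_survivors = names(screen$p)[screen$survivors],
                 spearman = prune, scaler = scaler, lasso = lasso,
                 selected = lasso$selected),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf(
    "selection_trace: %d screen survivors -> %d after pruning -> %d selected\n",
    length(x$utest_survivors),
    if (is.null(x$spearman)) 0L else length(x$spearman$kept),
    length(x$selected)))
  invisible(x)
}
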