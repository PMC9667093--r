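#' Pearson correlation matrix of node time series
#'
#' @param timeseries Numeric timepoints x nodes matrix (>= 3 timepoints,
#'   every column with nonzero variance).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(timeseries) {
  ts <- as.matrix(timeseries)
  if (nrow(ts) < 3) stop("need at least 3 timepoints", call. = FALSE)
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance node column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  r <- stats::cor(ts)
  (r + t(r)) / 2
}

#' Fisher r-to-z transform of a correlation matrix
#'
#' Applies `atanh` elementwise off the diagonal; the diagonal is set to 0.
#' Correlations with `|r| >= 1 - 1e-7` are clipped before the transform
#' (with a warning) so the result stays finite.
#'
#' @param r Symmetric correlation matrix.
#' @return Symmetric matrix of z values with zero diagonal.
#' @export
fisher_z <- function(r) {
  r <- as.matrix(r)
  stopifnot(nrow(r) == ncol(r))
  clip <- 1 - 1e-7
  off <- row(r) != col(r)
  if (any(abs(r[off]) >= clip)) {
    warning("correlations with |r| >= 1 - 1e-7 clipped before atanh")
  }
  rc <- pmin(pmax(r, -clip), clip)
  z <- atanh(rc)
  diag(z) <- 0
  (z + t(z)) / 2
}

#' Sparsity-threshold grid
#'
#' @param from,to,by Grid limits and step; the default is 0.05 to 0.50 in
#'   steps of 0.05 (10 thresholds).
#' @return Object of class `threshold_grid`: the numeric vector of sparsity
#'   levels with a `step` attribute.
#' @export
threshold_grid <- function(from = 0.05, to = 0.50, by = 0.05) {
  values <- seq(from, to, by = by)
  if (any(values <= 0) || any(values > 1) || any(diff(values) <= 0)) {
    stop("sparsity levels must be strictly increasing in (0, 1]", call. = FALSE)
  }
  structure(values, step = by, class = c("threshold_grid", "numeric"))
}

#' Number of edges realizing a sparsity level
#'
#' Sparsity S is the ratio of existing edges to the maximum possible
#' `n(n-1)/2`; the realized count is S times that maximum, rounded half away
#' from zero, floored at 1.
#'
#' @param S Sparsity in (0, 1].
#' @param n_nodes Number of nodes.
#' @return Integer edge count.
#' @export
edge_count <- function(S, n_nodes) {
  stopifnot(S > 0, S <= 1, n_nodes >= 2)
  m_max <- n_nodes * (n_nodes - 1) / 2
  k <- max(1L, as.integer(round_half_up(S * m_max)))
  if (k > m_max) stop("edge count exceeds the maximum possible", call. = FALSE)
  k
}

#' Binarize a connectivity matrix over a sparsity grid
#'
#' For each sparsity level the `edge_count(S, n)` upper-triangular entries
#' with the largest connectivity values become edges, so graph density
#' matches S exactly and edge sets are nested across the grid. Ranking uses
#' signed values descending by default (strongest positive correlations
#' first); `rank = "absolute"` ranks by magnitude. Ties at the cutoff are
#' broken lexicographically on the upper-triangle (row, column) index, so
#' binarization is fully deterministic.
#'
#' @param z Symmetric connectivity matrix (zero or any constant diagonal).
#' @param grid A [threshold_grid()].
#' @param rank `"signed"` (default) or `"absolute"`.
#' @return Object of class `binary_graph_stack`: list with `adjacency`
#'   (named list of 0/1 matrices, one per threshold), `grid`, `edge_counts`.
#' @export
binarize_stack <- function(z, grid = threshold_grid(), rank = c("signed", "absolute")) {
  rank <- match.arg(rank)
  z <- as.matrix(z)
  n <- nrow(z)
  stopifnot(n == ncol(z), isTRUE(all.equal(z, t(z), tolerance = 1e-8)))
  ut <- which(upper.tri(z), arr.ind = TRUE)
  vals <- z[upper.tri(z)]
  key <- if (rank == "absolute") -abs(vals) else -vals
  ord <- order(key, ut[, 1], ut[, 2])
  ks <- vapply(as.numeric(grid), edge_count, integer(1), n_nodes = n)
  adjacency <- vector("list", length(grid))
  names(adjacency) <- format_threshold(as.numeric(grid))
  for (t in seq_along(grid)) {
    sel <- ord[seq_len(ks[t])]
    a <- matrix(0L, n, n)
    a[cbind(ut[sel, 1], ut[sel, 2])] <- 1L
    a <- a + t(a)
    dimnames(a) <- dimnames(z)
    adjacency[[t]] <- a
  }
  structure(list(adjacency = adjacency,
                 grid = grid,
                 edge_counts = stats::setNames(ks, names(adjacency))),
            class = "binary_graph_stack")
}

format_threshold <- function(S) sprintf("%.2f", S)
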