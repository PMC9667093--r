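#' @importFrom igraph graph_from_adjacency_matrix betweenness rewire
#'   keeping_degseq as_adjacency_matrix ecount
NULL

as_graph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected",
                                      diag = FALSE)
}

check_adjacency <- function(adj) {
  adj <- as.matrix(adj)
  n <- nrow(adj)
  stopifnot(n == ncol(adj), all(adj %in% c(0, 1)),
            all(adj == t(adj)), all(diag(adj) == 0))
  adj
}

# ---- dense internal kernels (no validation, no igraph construction) ----

# all-pairs unweighted shortest paths by repeated boolean matrix products:
# the first walk length connecting a pair is its geodesic distance
dense_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a == 1] <- 1
  reach <- a
  k <- 1
  while (k < n) {
    reach <- (reach %*% a) > 0
    new <- reach & !is.finite(d)
    if (!any(new)) break
    k <- k + 1
    d[new] <- k
  }
  d
}

# nodal clustering 2 t_i / (k_i (k_i - 1)); triangle count from diag(A^3)
dense_clustering <- function(a) {
  k <- rowSums(a)
  t2 <- rowSums((a %*% a) * a)  # = 2 * triangles at each node
  cc <- ifelse(k >= 2, t2 / (k * (k - 1)), 0)
  as.numeric(cc)
}

dense_lp <- function(d) {
  off <- d[row(d) != col(d)]
  fin <- off[is.finite(off)]
  if (length(fin) == 0) {
    stop("characteristic path length undefined: graph has no edges",
         call. = FALSE)
  }
  mean(fin)
}

dense_eglob <- function(d) {
  inv <- 1 / d[row(d) != col(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

dense_local_efficiency <- function(a) {
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1)
    if (length(nb) < 2) next
    out[i] <- dense_eglob(dense_distances(a[nb, nb, drop = FALSE]))
  }
  out
}

# ---- exported metric operations ----

#' Degree centrality
#'
#' @param adj Binary symmetric adjacency matrix, zero diagonal.
#' @return Integer vector of node degrees (row sums).
#' @export
degree_centrality <- function(adj) {
  adj <- check_adjacency(adj)
  as.integer(rowSums(adj))
}

#' Nodal clustering coefficient and its network mean
#'
#' `NCp(i) = 2 t_i / (k_i (k_i - 1))` with `t_i` the number of triangles at
#' node i; nodes of degree < 2 get 0. The network clustering coefficient Cp
#' is the unweighted mean over all nodes (including the zeros), not the
#' transitivity ratio.
#'
#' @param adj Binary symmetric adjacency matrix.
#' @return Numeric vector of nodal clustering coefficients.
#' @export
nodal_clustering <- function(adj) {
  dense_clustering(check_adjacency(adj))
}

#' Unweighted shortest-path length matrix
#'
#' Breadth-first distances; unreachable pairs are `Inf`, the diagonal 0.
#'
#' @param adj Binary symmetric adjacency matrix.
#' @return n x n numeric distance matrix.
#' @export
shortest_path_lengths <- function(adj) {
  adj <- check_adjacency(adj)
  d <- dense_distances(adj)
  dimnames(d) <- dimnames(adj)
  d
}

#' Characteristic path length
#'
#' Mean shortest-path length over reachable (finite) ordered off-diagonal
#' pairs only — the convention needed because sparsely thresholded graphs
#' are routinely disconnected.
#'
#' @param dist Distance matrix from [shortest_path_lengths()].
#' @return Scalar Lp.
#' @export
characteristic_path_length <- function(dist) {
  dense_lp(as.matrix(dist))
}

#' Global efficiency
#'
#' Mean of inverse shortest-path lengths over distinct pairs, with
#' `1/Inf = 0` for unreachable pairs.
#'
#' @param dist Distance matrix.
#' @return Scalar in \[0, 1\].
#' @export
global_efficiency <- function(dist) {
  dense_eglob(as.matrix(dist))
}

#' Nodal efficiency
#'
#' `Ne(i)` is the mean of `1/d(i, j)` over all `j != i`.
#'
#' @param dist Distance matrix.
#' @return Numeric vector over nodes.
#' @export
nodal_efficiency <- function(dist) {
  dist <- as.matrix(dist)
  inv <- 1 / dist
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (nrow(dist) - 1)
}

#' Nodal local efficiency and its network mean
#'
#' `NLe(i)` is the global efficiency of the subgraph induced by the
#' neighbours of i (0 when i has fewer than 2 neighbours); the network
#' local efficiency Elocal is the unweighted mean of NLe over all nodes.
#'
#' @param adj Binary symmetric adjacency matrix.
#' @return Numeric vector of nodal local efficiencies.
#' @export
nodal_local_efficiency <- function(adj) {
  dense_local_efficiency(check_adjacency(adj))
}

#' Normalized betweenness centrality
#'
#' Brandes betweenness divided by `(n - 1)(n - 2) / 2`, so values lie in
#' \[0, 1\].
#'
#' @param adj Binary symmetric adjacency matrix.
#' @return Numeric vector over nodes.
#' @export
betweenness_centrality <- function(adj) {
  adj <- check_adjacency(adj)
  n <- nrow(adj)
  if (n < 3) return(numeric(n))
  b <- igraph::betweenness(as_graph(adj), directed = FALSE, normalized = FALSE)
  as.numeric(b) / ((n - 1) * (n - 2) / 2)
}

#' Degree-preserving rewiring (double edge swaps)
#'
#' Maslov-Sneppen style null model: repeated double-edge swaps keep every
#' node's degree while randomizing topology. Rigid graphs for which no swap
#' is possible (e.g. complete graphs) come back unchanged.
#'
#' @param adj Binary symmetric adjacency matrix with >= 2 independent edges.
#' @param swaps_per_edge Accepted-swap budget per edge (default 10).
#' @param seed Integer seed.
#' @return Rewired adjacency matrix with the same degree sequence.
#' @export
rewire_preserving_degrees <- function(adj, swaps_per_edge = 10L, seed = 1L) {
  adj <- check_adjacency(adj)
  out <- rewire_graph_matrix(as_graph(adj), swaps_per_edge, seed)
  dimnames(out) <- dimnames(adj)
  out
}

rewire_graph_matrix <- function(g, swaps_per_edge, seed) {
  m <- igraph::ecount(g)
  if (m < 2) {
    out <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  } else {
    g2 <- with_seed(seed,
      igraph::rewire(g, igraph::keeping_degseq(niter = swaps_per_edge * m)))
    out <- as.matrix(igraph::as_adjacency_matrix(g2, sparse = FALSE))
  }
  storage.mode(out) <- "integer"
  out
}

#' Small-world indices against a degree-preserving null ensemble
#'
#' gamma = Cp / mean(Cp over rewired graphs), lambda = Lp / mean(Lp over
#' rewired graphs), sigma = gamma / lambda. Null graphs use the same
#' finite-pair Lp convention as the observed graph.
#'
#' @param adj Binary symmetric adjacency matrix.
#' @param n_random Number of rewired null graphs (default 100).
#' @param swaps_per_edge Swaps per edge for each null graph.
#' @param seed Integer seed (null graph k uses a seed derived from it).
#' @param degenerate What to do when the null-ensemble mean clustering is
#'   zero (possible for very sparse small graphs whose rewired versions
#'   carry no triangles): `"error"` (default) aborts; `"analytic"`
#'   substitutes the random-graph clustering expectation
#'   `mean(degree) / (n - 1)` as the gamma denominator.
#' @return List with `gamma`, `lambda`, `sigma`, `cp_rand`, `lp_rand`.
#' @export
small_world_indices <- function(adj, n_random = 100L, swaps_per_edge = 10L,
                                seed = 1L,
                                degenerate = c("error", "analytic")) {
  degenerate <- match.arg(degenerate)
  adj <- check_adjacency(adj)
  cp <- mean(dense_clustering(adj))
  lp <- dense_lp(dense_distances(adj))
  g <- as_graph(adj)
  cp_r <- lp_r <- numeric(n_random)
  for (k in seq_len(n_random)) {
    r <- rewire_graph_matrix(g, swaps_per_edge, seed = derive_seed(seed, k))
    cp_r[k] <- mean(dense_clustering(r))
    lp_r[k] <- dense_lp(dense_distances(r))
  }
  denom_cp <- mean(cp_r)
  if (denom_cp == 0 && degenerate == "analytic") {
    denom_cp <- mean(rowSums(adj)) / (nrow(adj) - 1)
  }
  if (denom_cp == 0 || mean(lp_r) == 0) {
    stop("null-ensemble mean clustering or path length is zero; ",
         "small-world indices undefined", call. = FALSE)
  }
  gamma <- cp / denom_cp
  lambda <- lp / mean(lp_r)
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       cp_rand = cp_r, lp_rand = lp_r)
}

global_metric_names <- c("Cp", "Lp", "gamma", "lambda", "sigma",
                         "Eglobal", "Elocal")
nodal_metric_names <- c("NCp", "Ne", "NLe", "DC", "BC")

# all global + nodal metrics for one binary graph; assumes a valid
# adjacency (validated upstream by binarize_stack)
graph_metric_set <- function(adj, n_random = 100L, swaps_per_edge = 10L,
                             seed = 1L) {
  storage.mode(adj) <- "double"
  dist <- dense_distances(adj)
  ncp <- dense_clustering(adj)
  nle <- dense_local_efficiency(adj)
  n <- nrow(adj)
  bc <- if (n < 3) numeric(n) else {
    as.numeric(igraph::betweenness(as_graph(adj), directed = FALSE)) /
      ((n - 1) * (n - 2) / 2)
  }
  sw <- small_world_indices(adj, n_random, swaps_per_edge, seed,
                            degenerate = "analytic")
  list(
    global = c(Cp = mean(ncp),
               Lp = dense_lp(dist),
               gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma,
               Eglobal = dense_eglob(dist),
               Elocal = mean(nle)),
    nodal = rbind(NCp = ncp,
                  Ne = nodal_efficiency(dist),
                  NLe = nle,
                  DC = rowSums(adj),
                  BC = bc)
  )
}

#' Compute the full metric panel for a set of subjects
#'
#' For each subject: Pearson correlation of the time series, Fisher r-to-z,
#' binarization over the sparsity grid, then seven global and five nodal
#' metrics per threshold. Small-world normalization uses a
#' degree-preserving rewired ensemble seeded deterministically per
#' (subject, threshold) from `seed`; ensembles whose mean clustering is
#' zero (possible only for very sparse small graphs) fall back to the
#' analytic random-graph clustering expectation for the gamma denominator.
#'
#' @param timeseries Named list of timepoints x nodes matrices (or a
#'   `synthetic_cohort`, whose time series are used).
#' @param grid A [threshold_grid()].
#' @param n_random Null-ensemble size per graph (default 100; reduce for
#'   desk-scale runs).
#' @param swaps_per_edge Rewiring intensity.
#' @param seed Master seed for the null ensembles.
#' @param rank Edge-ranking rule passed to [binarize_stack()].
#' @return Object of class `metric_panel`: list with `global`
#'   (subject x threshold x 7 array), `nodal` (subject x threshold x 5 x
#'   node array), `grid`, `subjects`, `node_labels`.
#' @export
compute_metric_panel <- function(timeseries, grid = threshold_grid(),
                                 n_random = 100L, swaps_per_edge = 10L,
                                 seed = 1L, rank = "signed") {
  if (inherits(timeseries, "synthetic_cohort")) {
    timeseries <- timeseries$timeseries
  }
  stopifnot(is.list(timeseries), length(timeseries) >= 1)
  subjects <- names(timeseries)
  if (is.null(subjects)) subjects <- sprintf("sub%03d", seq_along(timeseries))
  n_nodes <- ncol(timeseries[[1]])
  node_labels <- colnames(timeseries[[1]])
  if (is.null(node_labels)) node_labels <- sprintf("node%03d", seq_len(n_nodes))
  n_thr <- length(grid)
  thr_names <- format_threshold(as.numeric(grid))

  glob <- array(NA_real_, c(length(subjects), n_thr, length(global_metric_names)),
                dimnames = list(subjects, thr_names, global_metric_names))
  noda <- array(NA_real_, c(length(subjects), n_thr, length(nodal_metric_names),
                            n_nodes),
                dimnames = list(subjects, thr_names, nodal_metric_names,
                                node_labels))
  for (s in seq_along(timeseries)) {
    z <- fisher_z(pearson_matrix(timeseries[[s]]))
    stack <- binarize_stack(z, grid, rank = rank)
    for (t in seq_len(n_thr)) {
      ms <- graph_metric_set(stack$adjacency[[t]], n_random, swaps_per_edge,
                             seed = derive_seed(seed, s, t))
      glob[s, t, ] <- ms$global[global_metric_names]
      noda[s, t, , ] <- ms$nodal[nodal_metric_names, ]
    }
  }
  structure(list(global = glob, nodal = noda, grid = grid,
                 subjects = subjects, node_labels = node_labels),
            class = "metric_panel")
}
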