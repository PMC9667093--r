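# Independent brute-force oracles used to verify the graph-metric
# implementations. These deliberately use different algorithms from the
# package internals (Floyd-Warshall vs BFS products, pair enumeration vs
# matrix algebra, geodesic counting vs Brandes).

oracle_fw_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_clustering <- function(a) {
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (p in seq_len(k - 1)) {
      for (q in seq(p + 1, k)) {
        if (a[nb[p], nb[q]] == 1) tri <- tri + 1
      }
    }
    out[i] <- 2 * tri / (k * (k - 1))
  }
  out
}

oracle_local_efficiency <- function(a) {
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1)
    if (length(nb) < 2) next
    d <- oracle_fw_distances(a[nb, nb, drop = FALSE])
    inv <- 1 / d[row(d) != col(d)]
    inv[!is.finite(inv)] <- 0
    out[i] <- mean(inv)
  }
  out
}

# normalized betweenness by explicit geodesic counting over all pairs
oracle_betweenness <- function(a) {
  n <- nrow(a)
  d <- oracle_fw_distances(a)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (v in order(d[s, ])) {
      if (v == s || !is.finite(d[s, v])) next
      pred <- which(a[v, ] == 1 & d[s, ] == d[s, v] - 1)
      sigma[s, v] <- sum(sigma[s, pred])
    }
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      if (!is.finite(d[s, t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t]) {
          bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  bc / ((n - 1) * (n - 2) / 2)
}

random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  a[up] <- rbinom(length(up), 1L, p)
  a + t(a)
}

# partial correlation via inversion of the joint correlation matrix
oracle_partial_cor <- function(x, y, Z) {
  M <- cbind(x, y, Z)
  P <- solve(stats::cor(M))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# named small graphs
adj_path3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
adj_k3 <- matrix(1, 3, 3) - diag(3)
adj_k4 <- matrix(1, 4, 4) - diag(4)
adj_star13 <- rbind(c(0, 1, 1, 1), c(1, 0, 0, 0), c(1, 0, 0, 0), c(1, 0, 0, 0))
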