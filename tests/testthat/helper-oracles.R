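# Brute-force graph-metric oracles, independent of the igraph-backed
# implementation: Floyd-Warshall distances, triangle-count clustering,
# pair-formula betweenness (path counts by dynamic programming on BFS
# levels), and direct e/a modularity evaluation of a given partition.

oracle_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  D[adj == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

oracle_clustering <- function(adj) {
  k <- rowSums(adj)
  tri <- diag(adj %*% adj %*% adj) / 2
  c_i <- ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
  as.numeric(c_i)
}

# number of shortest paths between every pair, via DP in order of distance
oracle_path_counts <- function(adj, D) {
  n <- nrow(adj)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(D[s, ])
    for (t in ord) {
      if (t == s || !is.finite(D[s, t])) next
      preds <- which(adj[, t] == 1 & D[s, ] == D[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  sigma
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  D <- oracle_distances(adj)
  sigma <- oracle_path_counts(adj, D)
  b <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(D[s, t]) || sigma[s, t] == 0) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t]) {
          b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  b
}

oracle_modularity <- function(adj, membership) {
  m <- sum(adj) / 2
  if (m == 0) return(NA_real_)
  Q <- 0
  for (cc in unique(membership)) {
    in_c <- membership == cc
    e_cc <- sum(adj[in_c, in_c, drop = FALSE]) / 2 / m
    a_c <- sum(adj[in_c, , drop = FALSE]) / (2 * m)
    Q <- Q + e_cc - a_c^2
  }
  Q
}

oracle_global <- function(adj) {
  D <- oracle_distances(adj)
  d <- D[upper.tri(D)]
  finite <- is.finite(d)
  list(C = mean(oracle_clustering(adj)),
       L = if (any(finite)) mean(d[finite]) else NA_real_,
       E = mean(ifelse(finite, 1 / d, 0)),
       connected_fraction = mean(finite))
}

# ---- graph fixtures --------------------------------------------------------

adj_from_edges <- function(n, edges) {
  adj <- matrix(0L, n, n)
  for (e in edges) {
    adj[e[1], e[2]] <- 1L
    adj[e[2], e[1]] <- 1L
  }
  adj
}

star_graph <- function(n) {
  adj_from_edges(n, lapply(2:n, function(i) c(1L, i)))
}

path_graph <- function(n) {
  adj_from_edges(n, lapply(seq_len(n - 1), function(i) c(i, i + 1L)))
}

cycle_graph <- function(n) {
  adj_from_edges(n, c(lapply(seq_len(n - 1), function(i) c(i, i + 1L)),
                      list(c(n, 1L))))
}

complete_graph <- function(n) {
  adj <- matrix(1L, n, n); diag(adj) <- 0L
  adj
}

two_cliques <- function(k) {
  adj <- matrix(0L, 2 * k, 2 * k)
  adj[1:k, 1:k] <- 1L
  adj[(k + 1):(2 * k), (k + 1):(2 * k)] <- 1L
  diag(adj) <- 0L
  adj
}

random_adj <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  ut <- which(upper.tri(adj))
  adj[ut] <- as.integer(stats::runif(length(ut)) < p)
  adj + t(adj)
}

# all connected graphs with <= 7 nodes, one per isomorphism class
# (graph atlas ordering; metrics are permutation-equivariant, so one
# representative per class covers every labeling)
atlas_connected_graphs <- function() {
  out <- list()
  for (i in 1:1252) {
    g <- igraph::graph_from_atlas(i)
    if (igraph::vcount(g) >= 2 && igraph::ecount(g) >= 1 &&
        igraph::is_connected(g)) {
      out[[length(out) + 1L]] <-
        as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    }
  }
  out
}
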