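as_igraph <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
}

#' Node degree
#'
#' @param net a `binary_network`.
#' @return named integer vector: number of edges attached to each node.
#' @export
node_degree <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  stats::setNames(as.integer(rowSums(net$adjacency)), net$labels)
}

#' Nodal clustering coefficient
#'
#' Fraction of realized links among each node's neighbors:
#' `c_i = 2 t_i / (k_i (k_i - 1))`, where `t_i` counts triangles through
#' node i. Nodes with degree < 2 get 0.
#'
#' @param net a `binary_network`.
#' @return named numeric vector in \[0, 1\].
#' @export
nodal_clustering <- function(net) {
  g <- as_igraph(net)
  ci <- igraph::transitivity(g, type = "local", isolates = "zero")
  stats::setNames(ci, net$labels)
}

#' Nodal betweenness centrality
#'
#' Multiplicity-weighted count of all-pairs shortest paths passing through
#' each node, endpoints excluded; each unordered pair counted once,
#' unnormalized.
#'
#' @param net a `binary_network`.
#' @return named numeric vector of betweenness values.
#' @export
betweenness_centrality <- function(net) {
  g <- as_igraph(net)
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  stats::setNames(as.numeric(b), net$labels)
}

#' All-pairs shortest path lengths (hop counts)
#'
#' @param net a `binary_network`.
#' @return N x N matrix of breadth-first hop counts, `Inf` for unreachable
#'   pairs, zero diagonal.
#' @export
shortest_path_lengths <- function(net) {
  g <- as_igraph(net)
  D <- igraph::distances(g, algorithm = "unweighted")
  dimnames(D) <- list(net$labels, net$labels)
  D
}

#' Characteristic path length
#'
#' Mean shortest-path length over node pairs. On disconnected graphs the
#' mean runs over the finite-distance pairs only and the fraction of
#' connected pairs is reported alongside, so L stays finite while the
#' disconnection is visible.
#'
#' @param net a `binary_network`.
#' @param sp optional precomputed matrix from [shortest_path_lengths()].
#' @return list with `L` and `connected_fraction`.
#' @export
characteristic_path_length <- function(net, sp = NULL) {
  if (is.null(sp)) sp <- shortest_path_lengths(net)
  d <- sp[upper.tri(sp)]
  finite <- is.finite(d)
  if (!any(finite)) stop("graph has no edges: path length undefined", call. = FALSE)
  list(L = mean(d[finite]), connected_fraction = mean(finite))
}

#' Global efficiency
#'
#' Mean over node pairs of the inverse shortest-path length, with
#' `1/Inf = 0` for unreachable pairs; lies in \[0, 1\].
#'
#' @param net a `binary_network`.
#' @param sp optional precomputed matrix from [shortest_path_lengths()].
#' @return scalar efficiency.
#' @export
global_efficiency <- function(net, sp = NULL) {
  if (is.null(sp)) sp <- shortest_path_lengths(net)
  d <- sp[upper.tri(sp)]
  mean(ifelse(is.finite(d), 1 / d, 0))
}

#' Modularity of the best greedy partition
#'
#' Newman modularity `Q = sum_c (e_cc - a_c^2)` of the partition found by
#' deterministic fast-greedy agglomeration; the partition is returned with Q
#' so the optimizer's output is inspectable.
#'
#' @param net a `binary_network` with at least one edge.
#' @return list with `Q` and `membership` (integer community per node).
#' @export
graph_modularity <- function(net) {
  if (net$n_edges < 1) stop("modularity needs at least one edge", call. = FALSE)
  g <- as_igraph(net)
  bp <- best_greedy_partition(g)
  list(Q = bp$Q, membership = stats::setNames(bp$membership, net$labels))
}

# best cut of the fast-greedy dendrogram, rescored so Q and the returned
# partition are consistent (the summary Q of hierarchical communities can
# disagree with membership() at Q ~ 0)
best_greedy_partition <- function(g) {
  com <- igraph::cluster_fast_greedy(g)
  i_best <- which.max(com$modularity)
  k_best <- igraph::vcount(g) - i_best + 1L
  mem <- igraph::cut_at(com, no = k_best)
  list(Q = igraph::modularity(g, mem), membership = mem)
}

#' Degree-preserving rewiring (Maslov-Sneppen double-edge swaps)
#'
#' Randomizes the topology while keeping every node's degree fixed. Swaps
#' that would create self-loops or duplicate edges are rejected. Graphs with
#' fewer than 2 edges are returned unchanged.
#'
#' @param net a `binary_network`.
#' @param seed integer seed (the rewiring consumes R's RNG stream).
#' @param swaps_per_edge attempted swaps per edge (default 10).
#' @return a rewired `binary_network` with identical degree sequence.
#' @export
rewire_degree_preserving <- function(net, seed = NULL, swaps_per_edge = 10) {
  if (net$n_edges < 2) return(net)
  if (!is.null(seed)) set.seed(as.integer(seed))
  g <- as_igraph(net)
  g2 <- igraph::rewire(
    g, igraph::keeping_degseq(loops = FALSE,
                              niter = ceiling(swaps_per_edge * net$n_edges)))
  adj <- as.matrix(igraph::as_adjacency_matrix(g2, sparse = FALSE))
  storage.mode(adj) <- "integer"
  dimnames(adj) <- list(net$labels, net$labels)
  new_binary_network(adj, net$density)
}

#' Null-normalized clustering, path length and small-worldness
#'
#' `C_rand` and `L_rand` are means over `R` independent degree-preserving
#' rewired replicates (each from its own sub-seed); then
#' `C_norm = C / C_rand`, `L_norm = L / L_rand` and
#' `sigma = C_norm / L_norm`. A sigma above 1 indicates small-world
#' organization. If `C_rand` is 0 (possible at very low density) sigma is
#' returned as `NA` with a warning.
#'
#' @param net a `binary_network` with at least 2 edges.
#' @param R number of null replicates (default 50).
#' @param seed master seed for the null ensemble.
#' @param swaps_per_edge attempted swaps per edge in each replicate.
#' @return list with `C`, `L`, `C_rand`, `L_rand`, `C_rand_sd`, `L_rand_sd`,
#'   `C_norm`, `L_norm`, `sigma`, `R`.
#' @export
normalized_metrics <- function(net, R = 50L, seed = 1L, swaps_per_edge = 10) {
  if (net$n_edges < 2) stop("normalization needs at least 2 edges", call. = FALSE)
  R <- as.integer(R)
  stopifnot(R >= 1L)
  g <- as_igraph(net)
  C <- mean(igraph::transitivity(g, type = "local", isolates = "zero"))
  L <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  niter <- ceiling(swaps_per_edge * net$n_edges)
  null_C <- numeric(R); null_L <- numeric(R)
  for (r in seq_len(R)) {
    set.seed(derive_seed(seed, r))
    g2 <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = niter))
    null_C[r] <- mean(igraph::transitivity(g2, type = "local", isolates = "zero"))
    null_L[r] <- igraph::mean_distance(g2, directed = FALSE, unconnected = TRUE)
  }
  C_rand <- mean(null_C); L_rand <- mean(null_L)
  C_norm <- if (C_rand > 0) C / C_rand else NA_real_
  L_norm <- L / L_rand
  sigma <- if (is.na(C_norm)) NA_real_ else C_norm / L_norm
  if (is.na(sigma)) {
    warning("C_rand is zero: small-worldness undefined at this density")
  }
  list(C = C, L = L, C_rand = C_rand, L_rand = L_rand,
       C_rand_sd = stats::sd(null_C), L_rand_sd = stats::sd(null_L),
       C_norm = C_norm, L_norm = L_norm, sigma = sigma, R = R)
}

#' All global metrics of one binary network
#'
#' @param net a `binary_network`.
#' @param null_R number of rewired nulls for the normalized measures; 0
#'   skips normalization (C_norm, L_norm, sigma returned as NA).
#' @param seed master seed for the null ensemble.
#' @param swaps_per_edge attempted swaps per edge per null replicate.
#' @return one-row data.frame with columns `C`, `L`, `E`, `Q`,
#'   `connected_fraction`, `C_norm`, `L_norm`, `sigma`.
#' @export
global_metrics <- function(net, null_R = 0L, seed = 1L, swaps_per_edge = 10) {
  g <- as_igraph(net)
  sp <- igraph::distances(g, algorithm = "unweighted")
  d <- sp[upper.tri(sp)]
  finite <- is.finite(d)
  if (!any(finite)) stop("graph has no edges: path length undefined", call. = FALSE)
  out <- data.frame(
    C = mean(igraph::transitivity(g, type = "local", isolates = "zero")),
    L = mean(d[finite]),
    E = mean(ifelse(finite, 1 / d, 0)),
    Q = best_greedy_partition(g)$Q,
    connected_fraction = mean(finite),
    C_norm = NA_real_, L_norm = NA_real_, sigma = NA_real_)
  if (null_R > 0L) {
    nm <- normalized_metrics(net, R = null_R, seed = seed,
                             swaps_per_edge = swaps_per_edge)
    out$C_norm <- nm$C_norm; out$L_norm <- nm$L_norm; out$sigma <- nm$sigma
  }
  out
}

#' Global metrics along a density sweep
#'
#' Thresholds one absolute connectivity matrix at every density of the grid
#' and computes the global measures, sharing the edge ordering across
#' densities (the edge sets are nested when weights are distinct).
#'
#' @param am absolute connectivity matrix.
#' @param grid density grid from [build_density_grid()].
#' @param null_R rewired nulls per density for normalized measures (0 to skip).
#' @param seed master seed; per-density null ensembles use sub-seeds.
#' @param swaps_per_edge attempted swaps per edge per null replicate.
#' @return data.frame: one row per density with `degree`, `density` and the
#'   [global_metrics()] columns.
#' @export
density_sweep_metrics <- function(am, grid, null_R = 0L, seed = 1L,
                                  swaps_per_edge = 10) {
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    net <- threshold_by_density(am, grid$density[i])
    cbind(grid[i, c("degree", "density")],
          global_metrics(net, null_R = null_R,
                         seed = derive_seed(seed, i),
                         swaps_per_edge = swaps_per_edge))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ring lattice
#'
#' Circular lattice where each node links to its `nei` nearest neighbors on
#' each side (mean degree `2 * nei`); the canonical high-clustering,
#' long-path benchmark for small-worldness.
#'
#' @param n number of nodes.
#' @param nei neighbors per side.
#' @return a `binary_network`.
#' @export
ring_lattice <- function(n, nei = 3L) {
  g <- igraph::make_lattice(length = n, dim = 1, nei = nei, circular = TRUE)
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  storage.mode(adj) <- "integer"
  binary_network(adj)
}
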