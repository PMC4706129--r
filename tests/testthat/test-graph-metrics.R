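bn <- function(adj) binary_network(adj)

test_that("degree, clustering and betweenness match hand-derived values", {
  star <- bn(star_graph(5))
  expect_equal(unname(node_degree(star)), c(4L, 1L, 1L, 1L, 1L))
  expect_equal(unname(betweenness_centrality(star)), c(6, 0, 0, 0, 0))
  expect_equal(unname(nodal_clustering(star)), rep(0, 5))

  comp <- bn(complete_graph(5))
  expect_equal(unname(node_degree(comp)), rep(4L, 5))
  expect_equal(unname(nodal_clustering(comp)), rep(1, 5))
  expect_equal(unname(betweenness_centrality(comp)), rep(0, 5))

  tri <- bn(complete_graph(3))
  expect_equal(unname(nodal_clustering(tri)), rep(1, 3))
  p3 <- bn(path_graph(3))
  expect_equal(unname(nodal_clustering(p3)), rep(0, 3))
  p4 <- bn(path_graph(4))
  expect_equal(unname(betweenness_centrality(p4)), c(0, 2, 2, 0))

  # 4-clique minus one edge: degree-3 nodes c = 2/3, degree-2 nodes c = 1
  adj <- complete_graph(4); adj[3, 4] <- adj[4, 3] <- 0L
  ci <- nodal_clustering(bn(adj))
  expect_equal(unname(ci), c(2 / 3, 2 / 3, 1, 1))
})

test_that("shortest paths, L and E follow the disconnection conventions", {
  comp <- bn(complete_graph(4))
  sp <- shortest_path_lengths(comp)
  expect_true(all(sp[upper.tri(sp)] == 1))
  expect_equal(characteristic_path_length(comp)$L, 1)
  expect_equal(global_efficiency(comp), 1)

  cyc <- bn(cycle_graph(4))
  expect_equal(characteristic_path_length(cyc)$L, 4 / 3)
  expect_equal(global_efficiency(cyc), 5 / 6)

  dyads <- bn(adj_from_edges(4, list(c(1, 2), c(3, 4))))
  sp2 <- shortest_path_lengths(dyads)
  expect_true(is.infinite(sp2[1, 3]))
  expect_equal(sp2[1, 2], 1)

  tri2 <- bn(two_cliques(3))
  cl <- characteristic_path_length(tri2)
  expect_equal(cl$L, 1)
  expect_equal(cl$connected_fraction, 6 / 15)

  empty <- bn(matrix(0L, 3, 3))
  expect_error(characteristic_path_length(empty), "no edges")
  expect_equal(global_efficiency(empty), 0)
})

test_that("closed forms hold: even cycles, complete graphs", {
  for (n in c(4, 6, 8, 10)) {
    expect_equal(characteristic_path_length(bn(cycle_graph(n)))$L,
                 (n^2 / 4) / (n - 1))
  }
  for (n in c(4, 7)) {
    expect_equal(mean(nodal_clustering(bn(complete_graph(n)))), 1)
    expect_equal(global_efficiency(bn(complete_graph(n))), 1)
  }
})

test_that("modularity returns the partition it scores", {
  tc <- bn(two_cliques(5))
  res <- graph_modularity(tc)
  expect_equal(res$Q, 0.5)
  expect_equal(length(unique(res$membership)), 2L)
  expect_equal(oracle_modularity(tc$adjacency, res$membership), res$Q)

  comp <- bn(complete_graph(6))
  expect_lte(graph_modularity(comp)$Q, 1e-12)
  expect_error(graph_modularity(bn(matrix(0L, 3, 3))), "edge")

  # single-community partition scores exactly zero
  adj <- random_adj(12, 0.3, seed = 5)
  expect_equal(oracle_modularity(adj, rep(1L, 12)), 0)
})

test_that("metrics agree with brute-force oracles on random graphs", {
  set.seed(10)
  for (rep in 1:20) {
    adj <- random_adj(10, runif(1, 0.2, 0.6), seed = 100 + rep)
    if (sum(adj) == 0) next
    net <- bn(adj)
    expect_equal(unname(node_degree(net)), rowSums(adj))
    expect_equal(unname(nodal_clustering(net)), oracle_clustering(adj))
    expect_equal(unname(betweenness_centrality(net)), oracle_betweenness(adj),
                 tolerance = 1e-10)
    expect_equal(unname(shortest_path_lengths(net)), unname(oracle_distances(adj)))
  }
})

test_that("rewiring preserves the degree sequence and randomizes structure", {
  tri <- bn(complete_graph(3))
  rw <- rewire_degree_preserving(tri, seed = 1)
  expect_identical(rw$adjacency, tri$adjacency)  # no valid swap exists

  for (s in 1:5) {
    adj <- random_adj(30, 0.2, seed = 200 + s)
    net <- bn(adj)
    rw <- rewire_degree_preserving(net, seed = s)
    expect_identical(sort(unname(node_degree(rw))),
                     sort(unname(node_degree(net))))
    expect_identical(unname(node_degree(rw)), unname(node_degree(net)))
  }

  lattice <- ring_lattice(100, 3)
  null_c <- mean(replicate(20, {
    mean(nodal_clustering(rewire_degree_preserving(lattice,
                                                   seed = sample.int(1e6, 1))))
  }))
  expect_lt(null_c, mean(nodal_clustering(lattice)))
})

test_that("null normalization is reproducible and self-consistent", {
  er <- bn(random_adj(100, 0.06, seed = 77))
  nm1 <- normalized_metrics(er, R = 20, seed = 5)
  nm2 <- normalized_metrics(er, R = 20, seed = 5)
  expect_identical(nm1, nm2)
  # a random graph is its own null: normalized scores sit near 1
  expect_lte(abs(nm1$C - nm1$C_rand), 3 * nm1$C_rand_sd)
  expect_lte(abs(nm1$L - nm1$L_rand), 3 * nm1$L_rand_sd)
  one <- normalized_metrics(er, R = 1, seed = 9)
  expect_identical(one, normalized_metrics(er, R = 1, seed = 9))

  lattice <- ring_lattice(100, 3)
  nm <- normalized_metrics(lattice, R = 20, seed = 3)
  expect_gt(nm$sigma, 1)
})

test_that("efficiency rises and path length falls along the density sweep", {
  set.seed(11)
  ts <- matrix(rnorm(50 * 30), 50, 30)
  am <- absolute_matrix(pearson_matrix(ts))
  grid <- build_density_grid(30, 3, 20)
  sweep <- density_sweep_metrics(am, grid)
  expect_equal(nrow(sweep), 18L)
  expect_true(all(diff(sweep$E) >= -1e-12))
  conn <- sweep$connected_fraction == 1
  expect_true(all(diff(sweep$L[conn]) <= 1e-12))
})
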