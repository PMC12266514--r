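path_net <- function() {
  coexpression_network(c("a", "b", "c"),
                       data.frame(from = c("a", "b"), to = c("b", "c"),
                                  weight = c(1, 1)))
}

star_net <- function() {
  coexpression_network(c("h", "l1", "l2", "l3", "l4"),
                       data.frame(from = rep("h", 4),
                                  to = paste0("l", 1:4),
                                  weight = rep(1, 4)))
}

test_that("centralities match hand values on path and star graphs", {
  cen <- node_centralities(path_net())
  b <- cen[cen$gene == "b", ]
  expect_equal(b$degree, 2)
  expect_equal(b$betweenness, 1)     # the only (a, c) pair passes b
  expect_equal(b$closeness, 1)       # distances 1 and 1
  expect_equal(b$degree_rank, 1)
  expect_equal(cen$degree_rank[cen$gene == "a"], 2)

  star <- node_centralities(star_net())
  h <- star[star$gene == "h", ]
  expect_equal(h$betweenness, 1)     # all C(4,2) leaf pairs pass the hub
  expect_equal(h$closeness, 1)
  expect_equal(star$betweenness[star$gene == "l1"], 0)
})

test_that("centralities equal brute-force enumeration on random graphs", {
  for (seed in 1:5) {
    a <- random_adjacency(30, 0.12, seed)
    net <- adjacency_to_network(a)
    cen <- node_centralities(net)
    expect_equal(cen$betweenness, bf_betweenness(a), tolerance = 1e-9)
    expect_equal(cen$closeness, bf_closeness(a), tolerance = 1e-9)
    expect_equal(cen$degree, rowSums(a))
  }
})

test_that("an edgeless network yields zero centralities", {
  net <- coexpression_network(letters[1:4],
                              data.frame(from = character(),
                                         to = character(),
                                         weight = numeric()))
  cen <- node_centralities(net)
  expect_true(all(cen$degree == 0 & cen$betweenness == 0 &
                  cen$closeness == 0))
})

test_that("size metrics follow the printed formulas", {
  k3 <- adjacency_to_network(matrix(1, 3, 3) - diag(3))
  m3 <- network_size_metrics(k3)
  expect_equal(m3$density, 1)
  expect_equal(m3$transitivity, 1)
  expect_equal(m3$avg_clustering, 1)

  star <- network_size_metrics(star_net())
  expect_equal(star$density, 2 * 4 / (5 * 4))
  expect_equal(star$transitivity, 0)
  expect_equal(star$avg_clustering, 0)

  for (n in c(4, 6)) {                  # K_n: density and transitivity 1
    kn <- adjacency_to_network(matrix(1, n, n) - diag(n))
    mm <- network_size_metrics(kn)
    expect_equal(mm$density, 1)
    expect_equal(mm$transitivity, 1)
  }
})

test_that("size metrics equal brute-force triangle/triad counting", {
  for (seed in 1:5) {
    a <- random_adjacency(40, 0.1, seed + 50)
    got <- network_size_metrics(adjacency_to_network(a))
    oracle <- bf_graph_metrics(a)
    expect_equal(got$density, oracle$density, tolerance = 1e-12)
    expect_equal(got$transitivity, oracle$transitivity, tolerance = 1e-12)
    expect_equal(got$avg_clustering, oracle$avg_clustering,
                 tolerance = 1e-12)
    expect_equal(got$n_triangles, oracle$n_triangles)
  }
})

test_that("community detection separates two cliques joined by one edge", {
  a <- matrix(0, 10, 10)
  a[1:5, 1:5] <- 1; a[6:10, 6:10] <- 1; diag(a) <- 0
  a[5, 6] <- a[6, 5] <- 1
  net <- adjacency_to_network(a)
  part <- detect_communities(net, seed = 3)
  expect_length(unique(part$community), 2)
  expect_length(unique(part$community[1:5]), 1)
  expect_length(unique(part$community[6:10]), 1)
  # determinism
  expect_identical(part$community, detect_communities(net, seed = 3)$community)
  # single clique collapses to one community
  k5 <- adjacency_to_network(matrix(1, 5, 5) - diag(5))
  expect_length(unique(detect_communities(k5, seed = 1)$community), 1)
})

test_that("the detected partition beats the trivial all-in-one modularity", {
  a <- random_adjacency(24, 0.18, 77)
  net <- adjacency_to_network(a)
  part <- detect_communities(net, seed = 2)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  expect_gte(igraph::modularity(g, part$community),
             igraph::modularity(g, rep(1, 24)))
})

test_that("edgeless networks fall back to singleton communities", {
  net <- coexpression_network(letters[1:5],
                              data.frame(from = character(),
                                         to = character(),
                                         weight = numeric()))
  expect_warning(part <- detect_communities(net), "edgeless")
  expect_length(unique(part$community), 5)
})

test_that("community gene sets respect the minimum size", {
  part <- data.frame(gene = sprintf("g%02d", 1:12),
                     community = c(rep(1, 7), rep(2, 3), rep(3, 2)))
  class(part) <- c("community_partition", "data.frame")
  expect_message(sets <- community_gene_sets(part, min_size = 5),
                 "skipping")
  expect_length(sets, 1)
  expect_length(sets[["1"]], 7)
})
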