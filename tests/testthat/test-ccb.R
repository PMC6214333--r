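test_that("modularity matches hand-derived and degenerate cases", {
  lay <- electrode_layout(c("u", "v"), c(0, 1), c(0, 0))
  M <- matrix(c(0, 0.5, 0.5, 0), 2, 2, dimnames = list(lay$label, lay$label))
  net <- coherence_network(lay, M, 0.1)
  g <- significant_graph(net)
  # both vertices in one community: Q = 0 by hand expansion
  expect_equal(modularity_q(g, fu_partition(list(c("u", "v")))), 0)
  # all-singleton partition: Q = -sum K_v^2 / (4 m^2)
  p0 <- fu_partition(list("u", "v"))
  K <- rowSums(g$W); m <- sum(g$W) / 2
  expect_equal(modularity_q(g, p0), -sum(K^2) / (4 * m^2))
  # zero-weight graph is an error
  g0 <- significant_graph(net, theta = 0.9)
  expect_error(modularity_q(g0, p0), "zero total weight")
})

test_that("modularity agrees with the double-sum oracle and igraph", {
  skip_if_not_installed("igraph")
  set.seed(11)
  for (rep in 1:10) {
    net <- random_grid_network(seed = 100 + rep)
    g <- significant_graph(net)
    member <- sample(1:3, 12, replace = TRUE)
    names(member) <- g$labels
    part <- fu_partition(member)
    q <- modularity_q(g, part)
    expect_equal(q, oracle_modularity(g$W, part$membership), tolerance = 1e-12)
    ig <- igraph::graph_from_adjacency_matrix(g$W, mode = "undirected",
                                              weighted = TRUE)
    expect_equal(q, igraph::modularity(ig, part$membership[g$labels],
                                       weights = igraph::E(ig)$weight),
                 tolerance = 1e-12)
  }
})

test_that("closed-form gain equals the modularity difference (oracle)", {
  set.seed(5)
  for (rep in 1:100) {
    net <- random_grid_network(seed = 3000 + rep)
    g <- significant_graph(net)
    if (sum(g$W) == 0) next
    member <- sample(1:4, 12, replace = TRUE)
    names(member) <- g$labels
    part <- fu_partition(member)
    v <- sample(g$labels, 1)
    target <- sample(seq_along(part$communities), 1)
    gain <- modularity_gain(g, part, v, target)
    after <- part$membership
    after[v] <- target
    q_before <- modularity_q(g, part)
    q_after <- modularity_q(g, fu_partition(after))
    expect_lt(abs(gain - (q_after - q_before)), 1e-10)
  }
})

test_that("gain of moving a vertex to its own community is zero", {
  g <- significant_graph(table1$network)
  part <- fu_partition(list(c("a", "b"), c("e", "f")),
                       labels = table1$layout$label)
  src <- part$membership[["a"]]
  expect_identical(modularity_gain(g, part, "a", src), 0)
  expect_error(modularity_gain(g, part, "zz", 1), "unknown vertex")
  expect_error(modularity_gain(g, part, "a", 99), "unknown community")
})

test_that("CCB reproduces the worked-example community cliques", {
  p <- ccb_detect(table1$network, table1$adjacency, debug = TRUE)
  expect_true(same_partition(p, fu_partition(list(
    c("a", "b", "e", "f", "i", "j"), c("d", "g", "h", "l"), "c", "k"))))
  # CCB's constrained optimum beats the MCB partition in modularity
  g <- significant_graph(table1$network)
  q_ccb <- modularity_q(g, p)
  q_mcb <- modularity_q(g, fu_partition(list(
    c("a", "b", "e", "f", "g", "i", "j"), c("d", "h", "l"), "c", "k")))
  expect_gt(q_ccb, q_mcb)
})

test_that("CCB on an edgeless network returns all singletons", {
  lay <- grid_layout(3L, 4L)
  M <- matrix(0.05, 12, 12, dimnames = list(lay$label, lay$label))
  diag(M) <- 0
  net <- coherence_network(lay, M, 0.2)
  p <- ccb_detect(net, voronoi_adjacency(lay))
  expect_identical(length(p$communities), 12L)
  expect_true(all(lengths(p$communities) == 1L))
})

test_that("every CCB community is a Voronoi-connected clique", {
  set.seed(21)
  for (rep in 1:20) {
    net <- random_grid_network(seed = 500 + rep, p_edge = 0.5)
    adj <- voronoi_adjacency(net$layout)
    p <- ccb_detect(net, adj, debug = TRUE) # debug asserts intermediates too
    W <- significant_graph(net)$W
    for (s in p$communities[lengths(p$communities) > 1L]) {
      sub <- W[s, s]
      expect_true(all(sub[upper.tri(sub)] > 0))
      expect_true(is_voronoi_connected(s, adj))
    }
  }
})

test_that("incremental and recomputed candidate bookkeeping agree", {
  for (seedv in c(7, 77, 777)) {
    net <- random_grid_network(seed = seedv, p_edge = 0.5)
    adj <- voronoi_adjacency(net$layout)
    p1 <- ccb_detect(net, adj, incremental = TRUE)
    p2 <- ccb_detect(net, adj, incremental = FALSE)
    expect_true(same_partition(p1, p2))
  }
})

test_that("CCB is deterministic and invariant to community relabeling", {
  net <- random_grid_network(seed = 4242, p_edge = 0.5)
  adj <- voronoi_adjacency(net$layout)
  p1 <- ccb_detect(net, adj)
  p2 <- ccb_detect(net, adj)
  expect_identical(p1$communities, p2$communities)
  # canonical form is independent of the internal label values
  relab <- fu_partition(p1$membership + 5L)
  expect_true(same_partition(p1, relab))
})
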