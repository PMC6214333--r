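test_that("layout validation rejects duplicates and names offenders", {
  expect_error(electrode_layout(c("A", "A"), c(0, 1), c(0, 0)), "A")
  expect_error(electrode_layout(c("A", "B"), c(1, 1), c(2, 2)),
               "duplicate electrode positions.*A, B")
  expect_error(electrode_layout(character(0), numeric(0), numeric(0)))
})

test_that("grid Voronoi adjacency is 4-connectivity; f's neighbors match", {
  adj <- voronoi_adjacency(fixture_layout("fig3-grid"))
  expect_identical(adj$neighbors$f, c("b", "e", "g", "j"))
  expect_identical(adj$neighbors$a, c("b", "e"))
  expect_identical(adj$neighbors$k, c("g", "j", "l"))
  # 3x4 grid has 2*(3*3) + ... = cols*(rows-1) + rows*(cols-1) = 17 pairs
  expect_identical(nrow(adj$pairs), 17L)
})

test_that("two electrodes are always Voronoi neighbors", {
  adj <- voronoi_adjacency(electrode_layout(c("u", "v"), c(0, 3), c(1, -2)))
  expect_identical(adj$pairs$u, "u")
  expect_identical(adj$pairs$v, "v")
})

test_that("collinear layouts give chain adjacency without crashing", {
  lay <- electrode_layout(c("p", "q", "r", "s"), 0:3, rep(0, 4))
  adj <- voronoi_adjacency(lay)
  expect_identical(paste(adj$pairs$u, adj$pairs$v),
                   c("p q", "q r", "r s"))
})

test_that("random layouts match the bisector-sampling oracle", {
  set.seed(42)
  for (rep in 1:6) {
    lay <- electrode_layout(sprintf("e%02d", 1:10), runif(10), runif(10))
    adj <- voronoi_adjacency(lay)
    got <- sort(paste(adj$pairs$u, adj$pairs$v, sep = "|"))
    expect_identical(got, oracle_voronoi_pairs(lay))
  }
})

test_that("adjacency is symmetric and irreflexive on random layouts", {
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(3:12, 1)
    lay <- electrode_layout(sprintf("e%02d", 1:n), runif(n), runif(n))
    adj <- voronoi_adjacency(lay)
    for (v in lay$label) {
      expect_false(v %in% adj$neighbors[[v]])
      for (u in adj$neighbors[[v]]) {
        expect_true(v %in% adj$neighbors[[u]])
      }
    }
    expect_gte(nrow(adj$pairs), 1L)
  }
})

test_that("Voronoi connectivity handles empty, singleton and split sets", {
  adj <- table1$adjacency
  expect_true(is_voronoi_connected(character(0), adj))
  expect_true(is_voronoi_connected("c", adj))
  expect_true(is_voronoi_connected(c("a", "b", "e", "f", "i", "j"), adj))
  expect_false(is_voronoi_connected(c("a", "d"), adj))
  expect_error(is_voronoi_connected("zz", adj), "unknown")
})

test_that("significance threshold follows 1 - p^(1/(L-1))", {
  # independent log/exp evaluation
  expect_equal(significance_threshold(0.01, 13),
               1 - exp(log(0.01) / 12), tolerance = 1e-14)
  expect_equal(significance_threshold(0.01, 13), 0.3187079, tolerance = 1e-6)
  expect_equal(significance_threshold(0.05, 2), 0.95)
  expect_lt(significance_threshold(1 - 1e-9, 13), 1e-9) # p -> 1 gives theta -> 0
  expect_error(significance_threshold(0.01, 1), "L")
  expect_error(significance_threshold(0, 13), "p")
})

test_that("thresholding at 0.2 reproduces the printed adjacency pattern", {
  g <- significant_graph(table1$network)
  expect_identical(nrow(g$edges), 27L)
  deg <- rowSums(g$W > 0)
  expect_identical(unname(deg[c("c", "k")]), c(0, 0))
  # spot checks of the 0/1 pattern rows (a and g)
  expect_identical(unname(g$W["a", ] > 0),
                   c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE,
                     TRUE, TRUE, FALSE, FALSE))
  expect_identical(unname(g$W["g", ] > 0),
                   c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE,
                     TRUE, TRUE, FALSE, TRUE))
})

test_that("edge set at theta = 0.7 is exactly the six printed pairs", {
  g <- significant_graph(table1$network, theta = 0.7)
  got <- sort(paste(g$edges$u, g$edges$v))
  expect_identical(got, sort(c("d g", "d h", "d l", "f g", "g l", "h l")))
})

test_that("edge count is non-increasing in theta and complete at 0", {
  thetas <- seq(0, 1, by = 0.05)
  counts <- vapply(thetas, function(th) {
    nrow(significant_graph(table1$network, theta = th)$edges)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
  npos <- sum(table1$network$coherence[upper.tri(table1$network$coherence)] > 0)
  expect_identical(counts[1L], npos)
  expect_identical(counts[length(counts)], 0L) # theta above max entry
})

test_that("local average coherence reproduces the printed ordering", {
  lav <- local_average_coherence(table1$network, table1$adjacency)
  expect_identical(lav$order,
                   c("h", "a", "f", "e", "b", "l", "d", "g", "i", "j", "c", "k"))
  expect_equal(unname(lav$values["h"]), (0.71 + 0.69 + 0.72) / 3,
               tolerance = 1e-12)
})

test_that("uniform coherence gives a constant local average", {
  lay <- grid_layout(2L, 3L)
  M <- matrix(0.4, 6, 6, dimnames = list(lay$label, lay$label))
  diag(M) <- 0
  net <- coherence_network(lay, M, 0.2)
  lav <- local_average_coherence(net, voronoi_adjacency(lay))
  expect_true(all(abs(lav$values - 0.4) < 1e-12))
  expect_identical(lav$order, sort(lay$label)) # ties broken by label
})

test_that("coherence network validation enforces its invariants", {
  lay <- grid_layout(2L, 2L)
  M <- matrix(0.5, 4, 4); diag(M) <- 0
  M[1, 2] <- 0.6 # asymmetric
  expect_error(coherence_network(lay, M, 0.2), "symmetric")
  M[1, 2] <- 0.5; M[1, 1] <- 0.1
  expect_error(coherence_network(lay, M, 0.2), "diagonal")
  M[1, 1] <- 0; M[2, 3] <- M[3, 2] <- 1.4
  expect_error(coherence_network(lay, M, 0.2), "\\[0, 1\\]")
})
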