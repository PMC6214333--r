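ccb_part <- ccb_detect(table1$network, table1$adjacency)

test_that("average coherence matches the printed worked-example values", {
  expect_equal(average_coherence(c("d", "h", "l"), table1$network), 0.71)
  expect_equal(average_coherence(c("h", "l"), table1$network), 0.72)
  expect_true(is.na(average_coherence("c", table1$network)))
  lay <- grid_layout(2L, 2L)
  M <- matrix(0.37, 4, 4, dimnames = list(lay$label, lay$label))
  diag(M) <- 0
  net <- coherence_network(lay, M, 0.1)
  expect_equal(average_coherence(c("a", "b", "c"), net), 0.37)
})

test_that("inter-FU coherence normalizes by the maximal edge count", {
  expect_equal(inter_fu_coherence("c", "k", table1$network), 0.10)
  expect_equal(inter_fu_coherence(c("a", "b", "e", "f", "i", "j"),
                                  c("g", "d", "h", "l"), table1$network),
               3.51 / 24)
  expect_error(inter_fu_coherence(c("a", "b"), c("b", "c"), table1$network),
               "overlap")
  expect_error(inter_fu_coherence(character(0), "a", table1$network),
               "non-empty")
})

test_that("inter-FU coherence is symmetric and equals a double-loop oracle", {
  set.seed(31)
  for (rep in 1:10) {
    net <- random_grid_network(seed = 600 + rep)
    s1 <- sample(net$layout$label, 4)
    s2 <- sample(setdiff(net$layout$label, s1), 3)
    got <- inter_fu_coherence(s1, s2, net)
    expect_identical(got, inter_fu_coherence(s2, s1, net))
    acc <- 0
    for (u in s1) for (v in s2) acc <- acc + net$coherence[u, v]
    expect_equal(got, acc / (length(s1) * length(s2)), tolerance = 1e-12)
    w1 <- average_coherence(s1, net)
    expect_gte(w1, 0); expect_lte(w1, 1)
    expect_gte(got, 0); expect_lte(got, 1)
  }
})

test_that("FU barycenters are the mean member positions", {
  summ <- fu_summary(ccb_part, table1$network)
  big <- summ[summ$size == 6L, ]
  sel <- match(c("a", "b", "e", "f", "i", "j"), table1$layout$label)
  expect_equal(big$bx, mean(table1$layout$x[sel]))
  expect_equal(big$by, mean(table1$layout$y[sel]))
})

test_that("FU map of the worked example: 2 displayed FUs, no line at theta", {
  spec <- build_fu_map(ccb_part, table1$network, display_min_size = 2L)
  expect_identical(length(spec$displayed), 2L)
  # only inter-FU value among displayed pairs is 0.14625 < theta = 0.2
  expect_identical(nrow(spec$lines), 0L)
  # lowering the line threshold to 0.1 draws exactly one line
  spec2 <- build_fu_map(ccb_part, table1$network, display_min_size = 2L,
                        line_threshold = 0.1)
  expect_identical(nrow(spec2$lines), 1L)
  expect_equal(spec2$lines$coherence, 0.14625)
})

test_that("all-singleton maps are all white with no circles or lines", {
  singles <- fu_partition(as.list(table1$layout$label))
  spec <- build_fu_map(singles, table1$network)
  expect_true(all(is.na(spec$gray)))
  expect_identical(nrow(spec$circles), 0L)
  expect_identical(nrow(spec$lines), 0L)
  d <- withr::local_tempdir()
  render_fu_map(spec, file.path(d, "singles.svg"))
  svg <- readLines(file.path(d, "singles.svg"))
  expect_identical(sum(grepl("<polygon", svg)), 12L)
  expect_identical(sum(grepl("<circle", svg)), 0L)
  expect_identical(sum(grepl("<line ", svg)), 0L)
})

test_that("adjacent displayed FUs never share a gray level", {
  set.seed(13)
  for (rep in 1:50) {
    net <- random_grid_network(seed = 1300 + rep)
    # random contiguous-ish partition: cut the grid into vertical strips
    k <- sample(2:4, 1)
    strips <- split(net$layout$label, cut(net$layout$x, k, labels = FALSE))
    part <- fu_partition(strips)
    spec <- build_fu_map(part, net, display_min_size = 1L)
    mem <- spec$membership
    adj <- voronoi_adjacency(net$layout)
    for (r in seq_len(nrow(adj$pairs))) {
      f1 <- mem[[adj$pairs$u[r]]]
      f2 <- mem[[adj$pairs$v[r]]]
      if (f1 != f2) expect_false(identical(spec$gray[f1], spec$gray[f2]))
    }
  }
})

test_that("SVG rendering is byte-stable and has one polygon per electrode", {
  spec <- build_fu_map(ccb_part, table1$network, display_min_size = 2L)
  d <- withr::local_tempdir()
  p1 <- file.path(d, "m1.svg"); p2 <- file.path(d, "m2.svg")
  render_fu_map(spec, p1)
  render_fu_map(spec, p2)
  expect_identical(readLines(p1), readLines(p2))
  svg <- readLines(p1)
  expect_identical(sum(grepl("<polygon", svg)), 12L)
  expect_identical(sum(grepl("<circle", svg)), 2L)
})

test_that("the 10-20 montage renders a 3-FU map without errors", {
  lay <- fixture_layout("montage-10-20")
  set.seed(17)
  n <- nrow(lay)
  M <- matrix(runif(n * n, 0, 0.15), n, n,
              dimnames = list(lay$label, lay$label))
  M <- (M + t(M)) / 2
  diag(M) <- 0
  fus <- list(c("Fp1", "F3", "Fz"), c("O1", "O2", "Pz"), c("C3", "T3"))
  for (s in fus) for (u in s) for (v in setdiff(s, u)) M[u, v] <- 0.8
  dimnames(M) <- list(lay$label, lay$label)
  net <- coherence_network(lay, (M + t(M)) / 2, 0.3)
  part <- fu_partition(fus, labels = lay$label)
  spec <- build_fu_map(part, net, display_min_size = 2L, boundary = "circle")
  d <- withr::local_tempdir()
  expect_no_error(render_fu_map(spec, file.path(d, "montage.svg")))
  expect_no_error(render_fu_map(spec, file.path(d, "montage.png"),
                                format = "png"))
  expect_no_error(write_fu_map_json(spec, file.path(d, "montage.json")))
  expect_true(file.size(file.path(d, "montage.png")) > 0)
})
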