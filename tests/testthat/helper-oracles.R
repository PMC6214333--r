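# Independent oracles and generators shared across tests. Each oracle is a
# deliberately naive computation kept independent of the package's code paths.

# Voronoi adjacency by bisector sampling: u and v are neighbors iff some
# point on their perpendicular bisector is strictly nearer to {u, v} than to
# every other site.
oracle_voronoi_pairs <- function(layout, nsample = 4001L, reach = 4) {
  pts <- cbind(layout$x, layout$y)
  n <- nrow(pts)
  diam <- max(stats::dist(pts))
  out <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- pts[i, ]; b <- pts[j, ]
      mid <- (a + b) / 2
      d <- b - a
      tang <- c(-d[2], d[1]) / sqrt(sum(d^2))
      ts <- seq(-reach * diam, reach * diam, length.out = nsample)
      px <- mid[1] + ts * tang[1]
      py <- mid[2] + ts * tang[2]
      dd <- outer(px, pts[, 1], "-")^2 + outer(py, pts[, 2], "-")^2
      nearest_other <- apply(dd[, -c(i, j), drop = FALSE], 1, min)
      if (any(dd[, i] < nearest_other - 1e-9 * diam^2)) {
        out <- c(out, paste(sort(c(layout$label[i], layout$label[j])),
                            collapse = "|"))
      }
    }
  }
  sort(out)
}

# Modularity straight from its defining double sum over ordered pairs.
oracle_modularity <- function(W, membership) {
  m <- sum(W) / 2
  K <- unname(rowSums(W))
  q <- 0
  n <- nrow(W)
  for (v in seq_len(n)) {
    for (v2 in seq_len(n)) {
      if (membership[v] == membership[v2]) {
        q <- q + W[v, v2] - K[v] * K[v2] / (2 * m)
      }
    }
  }
  q / (2 * m)
}

# All maximal Voronoi-connected cliques by exhaustive subset scan (n <= 14).
oracle_spatial_maximal_cliques <- function(graph, adjacency) {
  labels <- graph$labels
  n <- length(labels)
  Wpos <- graph$W > 0
  family <- list()
  for (code in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(code, 2^(seq_len(n) - 1L)) > 0L)
    s <- labels[idx]
    k <- length(s)
    if (k > 1L) {
      sub <- Wpos[s, s]
      if (!all(sub[upper.tri(sub)])) next
    }
    if (!is_voronoi_connected(s, adjacency)) next
    family[[length(family) + 1L]] <- sort(s)
  }
  maximal <- Filter(function(s) {
    !any(vapply(family, function(t) length(t) > length(s) && all(s %in% t),
                logical(1)))
  }, family)
  unique(maximal)
}

# Random coherence network on the 3x4 grid: each pair is an edge with
# probability p_edge (weight above theta) and sub-threshold otherwise.
random_grid_network <- function(seed, p_edge = 0.4, theta = 0.2) {
  set.seed(seed)
  layout <- grid_layout(3L, 4L)
  n <- nrow(layout)
  M <- matrix(0, n, n, dimnames = list(layout$label, layout$label))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      w <- if (stats::runif(1) < p_edge) stats::runif(1, theta, 1) else
        stats::runif(1, 0, theta * 0.95)
      M[i, j] <- w
      M[j, i] <- w
    }
  }
  coherence_network(layout, M, theta)
}

canonical_sets <- function(sets) {
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, paste, character(1), collapse = "|"))]
}

table1 <- table1_network()
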