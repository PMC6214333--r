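#' Weighted modularity of a partition
#'
#' Modularity of a partition of the significant coherence graph,
#' \deqn{Q = \frac{1}{2m}\sum_{v,v'}\left[c(v,v') -
#'   \frac{K_v K_{v'}}{2m}\right]\delta(L(v), L(v')),}
#' where the sum runs over ordered vertex pairs including `v = v'`
#' (`c(v,v) = 0`, but the null term `-K_v^2/2m` is counted), `K_v` is the
#' weighted degree, and `m` is half the total edge weight. `Q` measures the
#' within-community edge-weight fraction minus its expectation under random
#' reassignment of the weights; it lies in `[-1, 1]`.
#'
#' @param graph a [significant_graph()].
#' @param partition an [fu_partition()] covering the graph's vertices.
#' @return The modularity `Q`.
#' @export
modularity_q <- function(graph, partition) {
  stopifnot(inherits(graph, "significant_graph"),
            inherits(partition, "fu_partition"))
  W <- graph$W
  if (!setequal(names(partition$membership), graph$labels)) {
    stop("partition does not cover the graph's vertex set")
  }
  m <- sum(W) / 2
  if (m == 0) stop("graph has zero total weight; modularity undefined")
  K <- rowSums(W)
  q <- 0
  for (members in partition$communities) {
    q <- q + sum(W[members, members]) - sum(K[members])^2 / (2 * m)
  }
  q / (2 * m)
}

#' Modularity gain of a single-vertex move
#'
#' The exact change in [modularity_q()] caused by moving vertex `v` from its
#' current community to `target`, computed in closed form from the incident
#' weight sums and community degrees:
#' \deqn{\Delta Q = \frac{1}{m}\left(\sum_{l \in C_t} c(v,l) -
#'   \sum_{l \in C_s \setminus v} c(v,l)\right) -
#'   \frac{K_v (K_{C_t} - K_{C_s} + K_v)}{2 m^2},}
#' with `C_s` the source community (its degree sum `K_{C_s}` still includes
#' `v`) and `C_t` the target. The value equals
#' `modularity_q(after) - modularity_q(before)` exactly; moving a vertex to
#' its own community is the identity and returns 0.
#'
#' @param graph a [significant_graph()].
#' @param partition an [fu_partition()] over the graph's vertices.
#' @param v vertex label.
#' @param target canonical community id (index into `partition$communities`).
#' @return The modularity change `Delta Q`.
#' @export
modularity_gain <- function(graph, partition, v, target) {
  stopifnot(inherits(graph, "significant_graph"),
            inherits(partition, "fu_partition"))
  if (!v %in% graph$labels) stop("unknown vertex label: ", v)
  if (!target %in% seq_along(partition$communities)) {
    stop("unknown community id: ", target)
  }
  src <- partition$membership[[v]]
  if (src == target) return(0)
  W <- graph$W
  m <- sum(W) / 2
  if (m == 0) stop("graph has zero total weight; modularity undefined")
  K <- rowSums(W)
  Cs <- partition$communities[[src]]
  Ct <- partition$communities[[target]]
  S_t <- sum(W[v, Ct])
  S_s <- sum(W[v, setdiff(Cs, v)])
  (S_t - S_s) / m - K[[v]] * (sum(K[Ct]) - sum(K[Cs]) + K[[v]]) / (2 * m^2)
}

#' Community clique detection (CCB)
#'
#' Spatially constrained modularity optimization: starting from singleton
#' communities, vertices are visited in descending order of local average
#' coherence (ties by label) and moved to the admissible community with the
#' highest positive modularity gain, where a community is admissible for `v`
#' only if `v` is significantly connected to *every* member and has at least
#' one Voronoi neighbor among the members. A move is skipped when removing
#' `v` would leave its source community spatially disconnected. Passes over
#' all vertices repeat until a full pass makes no move. Every resulting
#' multi-member community is therefore a Voronoi-connected clique of the
#' significant graph (a *community clique*); vertices with no significant
#' edges remain singletons. There is no aggregation phase: communities stay
#' cliques of original electrodes.
#'
#' @param network a [coherence_network()].
#' @param adjacency a [voronoi_adjacency()] over the same layout.
#' @param incremental maintain the candidate bookkeeping sets (`H_i`:
#'   vertices connected to every member of community `i`; `R_i`: vertices
#'   with a Voronoi neighbor in `i`) incrementally across moves; with
#'   `FALSE` they are recomputed from scratch at every candidate check (the
#'   two modes are equivalent and tested as such).
#' @param debug verify after every accepted move that the tracked modularity
#'   matches [modularity_q()] to 1e-10, that modularity never decreased, and
#'   that all intermediate communities are Voronoi-connected cliques.
#' @return An [fu_partition()] with attributes `Q` (final modularity, `NA`
#'   when the significant graph is empty) and `n_moves`.
#' @examples
#' tbl <- table1_network()
#' ccb_detect(tbl$network, tbl$adjacency)
#' @export
ccb_detect <- function(network, adjacency, incremental = TRUE, debug = FALSE) {
  stopifnot(inherits(network, "coherence_network"),
            inherits(adjacency, "voronoi_adjacency"))
  labels <- network$layout$label
  if (!identical(labels, adjacency$labels)) {
    stop("network and adjacency are over different layouts")
  }
  n <- length(labels)
  W <- network$coherence
  W[W < network$theta] <- 0
  A <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  for (v in labels) A[v, adjacency$neighbors[[v]]] <- TRUE
  m <- sum(W) / 2
  if (m == 0) {
    out <- fu_partition(stats::setNames(seq_len(n), labels))
    attr(out, "Q") <- NA_real_
    attr(out, "n_moves") <- 0L
    return(out)
  }
  K <- rowSums(W)
  lav <- local_average_coherence(network, adjacency)
  ord <- match(lav$order, labels)

  comm <- as.list(seq_len(n))          # member indices per community
  L <- seq_len(n)                      # community of each vertex
  Kc <- K                              # summed degree per community
  Wpos <- W > 0
  H <- lapply(seq_len(n), function(i) Wpos[, i])   # connected to all members
  R <- lapply(seq_len(n), function(i) A[, i])      # >=1 Voronoi neighbor
  recompute_HR <- function(members) {
    if (length(members) == 0L) {
      return(list(H = rep(FALSE, n), R = rep(FALSE, n)))
    }
    h <- rowSums(Wpos[, members, drop = FALSE]) == length(members)
    r <- rowSums(A[, members, drop = FALSE]) > 0
    list(H = h, R = r)
  }

  Q <- if (debug) modularity_q(significant_graph(network),
                               fu_partition(stats::setNames(L, labels))) else NA_real_
  n_moves <- 0L
  repeat {
    moved <- FALSE
    for (v in ord) {
      src <- L[v]
      rem <- setdiff(comm[[src]], v)
      if (length(rem) > 1L && !vor_connected_idx(rem, A)) next
      S_s <- sum(W[v, rem])
      Kc_s <- Kc[src]
      maxdq <- 0
      dest <- 0L
      for (j in seq_len(n)) {
        if (j == src) next
        members <- comm[[j]]
        if (length(members) == 0L) next
        if (incremental) {
          if (!H[[j]][v] || !R[[j]][v]) next
        } else {
          if (!all(Wpos[v, members]) || !any(A[v, members])) next
        }
        dq <- (sum(W[v, members]) - S_s) / m -
          K[v] * (Kc[j] - Kc_s + K[v]) / (2 * m^2)
        if (dq > maxdq) {
          maxdq <- dq
          dest <- j
        }
      }
      if (dest > 0L) {
        comm[[src]] <- rem
        comm[[dest]] <- c(comm[[dest]], v)
        L[v] <- dest
        Kc[src] <- Kc[src] - K[v]
        Kc[dest] <- Kc[dest] + K[v]
        hr <- recompute_HR(rem)
        H[[src]] <- hr$H
        R[[src]] <- hr$R
        H[[dest]] <- H[[dest]] & Wpos[, v]
        R[[dest]] <- R[[dest]] | A[, v]
        moved <- TRUE
        n_moves <- n_moves + 1L
        if (debug) {
          Qnew <- Q + maxdq
          part <- fu_partition(stats::setNames(L, labels))
          Qfull <- modularity_q(significant_graph(network), part)
          stopifnot(abs(Qnew - Qfull) < 1e-10, Qnew >= Q - 1e-12)
          Q <- Qnew
          for (members in comm[lengths(comm) > 1L]) {
            lbl <- labels[members]
            sub <- W[lbl, lbl]
            stopifnot(all(sub[upper.tri(sub)] > 0),
                      vor_connected_idx(members, A))
          }
        }
      }
    }
    if (!moved) break
  }
  out <- fu_partition(stats::setNames(L, labels))
  attr(out, "Q") <- modularity_q(significant_graph(network), out)
  attr(out, "n_moves") <- n_moves
  out
}

#' @rdname ccb_detect
#' @export
detect_community_cliques <- ccb_detect
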