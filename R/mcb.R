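#' Enumerate Voronoi-connected maximal cliques
#'
#' Recursively enumerates exactly the cliques of the significant graph that
#' are Voronoi-connected and maximal *within the family of Voronoi-connected
#' cliques* (a returned set may be a proper subset of some larger, spatially
#' disconnected clique). The recursion is a spatially constrained
#' Bron-Kerbosch: the growing clique `compsub` can only be extended through
#' `currentcand` (candidates Voronoi-adjacent to a member), while
#' `complcand` holds candidates connected to all members but not yet
#' spatially reachable; when the newly added vertex `v` has Voronoi
#' neighbors in `complcand` they move into `currentcand`. A branch reports
#' `compsub` when both the candidate set and the `not` set (previously
#' expanded vertices still connected to every member) are exhausted.
#'
#' @param graph a [significant_graph()].
#' @param adjacency a [voronoi_adjacency()] over the same label set.
#' @param tie how to pick among candidates with equally many graph
#'   connections to the remaining candidates: `"label"` (ascending label,
#'   the reproducible default) or `"random"`.
#' @return A list of sorted character vectors (including singleton maximal
#'   cliques, i.e. isolated vertices), ordered by first member then size.
#' @export
enumerate_spatial_maximal_cliques <- function(graph, adjacency,
                                              tie = c("label", "random")) {
  stopifnot(inherits(graph, "significant_graph"),
            inherits(adjacency, "voronoi_adjacency"))
  tie <- match.arg(tie)
  labels <- graph$labels
  if (!setequal(labels, adjacency$labels)) {
    stop("graph and adjacency are over different label sets")
  }
  n <- length(labels)
  Wpos <- graph$W > 0
  A <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  for (v in labels) A[v, adjacency$neighbors[[v]]] <- TRUE
  N <- lapply(seq_len(n), function(i) which(Wpos[i, ]))
  Vor <- lapply(seq_len(n), function(i) which(A[i, ]))
  found <- list()

  pick <- function(cand, pool) {
    # candidate with most graph connections to the other candidates
    score <- vapply(cand, function(v) sum(Wpos[v, setdiff(pool, v)]), numeric(1))
    best <- cand[score == max(score)]
    if (length(best) == 1L) return(best)
    if (tie == "label") best[order(labels[best])][1L] else sample(best, 1L)
  }

  extend <- function(compsub, cur, compl, notset) {
    if (length(cur) == 0L) {
      # a `not` vertex disproves maximality only if it could actually extend
      # compsub: it is connected to every member by construction, but must
      # also be Voronoi-adjacent to one (members of `not` inherited from the
      # top-level start order need this check; within-branch ones pass it)
      extender <- length(notset) > 0L &&
        any(A[notset, compsub, drop = FALSE])
      if (!extender) found[[length(found) + 1L]] <<- compsub
      return(invisible())
    }
    while (length(cur) > 0L) {
      v <- pick(cur, c(cur, compl))
      lambda <- intersect(compl, intersect(N[[v]], Vor[[v]]))
      newcur <- union(intersect(setdiff(cur, v), N[[v]]), lambda)
      newcompl <- setdiff(intersect(compl, N[[v]]), lambda)
      newnot <- intersect(notset, N[[v]])
      extend(c(compsub, v), newcur, newcompl, newnot)
      cur <- setdiff(cur, v)
      notset <- c(notset, v)
    }
    invisible()
  }

  # top level: branch per start vertex in descending significant-graph degree
  # (ties by label); vertices already expanded go to the `not` set
  deg <- rowSums(Wpos)
  start_order <- order(-deg, labels)
  done <- integer(0)
  for (v in start_order) {
    cur <- intersect(setdiff(N[[v]], done), Vor[[v]])
    compl <- setdiff(setdiff(N[[v]], done), Vor[[v]])
    notset <- intersect(done, N[[v]])
    extend(v, cur, compl, notset)
    done <- c(done, v)
  }
  out <- lapply(found, function(idx) sort(labels[idx]))
  out <- unique(out)
  out[order(vapply(out, `[`, character(1), 1L), lengths(out))]
}

#' Total strength of an electrode set
#'
#' The sum of significant edge weights with both endpoints in `members`.
#' Used to resolve vertices shared between overlapping maximal cliques:
#' a shared vertex is kept in the clique with the largest total strength.
#'
#' @param members character vector of electrode labels.
#' @param graph a [significant_graph()].
#' @return The summed weight (0 for empty or singleton sets).
#' @export
total_strength <- function(members, graph) {
  stopifnot(inherits(graph, "significant_graph"))
  members <- as.character(members)
  unknown <- setdiff(members, graph$labels)
  if (length(unknown)) stop("unknown labels: ", paste(unknown, collapse = ", "))
  if (length(members) < 2L) return(0)
  sub <- graph$W[members, members]
  sum(sub[upper.tri(sub)])
}

#' Maximal clique based FU detection (MCB)
#'
#' Enumerates the Voronoi-connected maximal cliques of the significant graph
#' and resolves overlaps by *total strength*: a vertex belonging to several
#' cliques is kept only in the clique whose total strength is largest (ties:
#' the clique whose smallest member label sorts first). The residual sets are
#' kept as FUs even when no longer maximal; if removing shared vertices
#' leaves a residual FU spatially disconnected, it is kept and a warning is
#' emitted. Vertices in no multi-vertex clique become singletons.
#'
#' @inheritParams ccb_detect
#' @param tie candidate tie rule passed to
#'   [enumerate_spatial_maximal_cliques()].
#' @return An [fu_partition()] with attribute `cliques` (the enumerated
#'   multi-vertex cliques before overlap resolution).
#' @examples
#' tbl <- table1_network()
#' mcb_detect(tbl$network, tbl$adjacency)
#' @export
mcb_detect <- function(network, adjacency, tie = c("label", "random")) {
  stopifnot(inherits(network, "coherence_network"))
  graph <- significant_graph(network)
  cliques <- enumerate_spatial_maximal_cliques(graph, adjacency, tie = tie)
  multi <- cliques[lengths(cliques) > 1L]
  strength <- vapply(multi, total_strength, numeric(1), graph = graph)
  firsts <- vapply(multi, `[`, character(1), 1L)
  labels <- network$layout$label
  assigned <- lapply(multi, identity)
  for (v in labels) {
    inwhich <- which(vapply(multi, function(s) v %in% s, logical(1)))
    if (length(inwhich) > 1L) {
      keep <- inwhich[order(-strength[inwhich], firsts[inwhich])][1L]
      for (j in setdiff(inwhich, keep)) {
        assigned[[j]] <- setdiff(assigned[[j]], v)
      }
    }
  }
  assigned <- assigned[lengths(assigned) > 0L]
  for (s in assigned) {
    if (length(s) > 1L && !is_voronoi_connected(s, adjacency)) {
      warning("MCB residual FU {", paste(s, collapse = ","),
              "} is no longer Voronoi-connected after shared-vertex removal")
    }
  }
  out <- fu_partition(assigned, labels = labels)
  attr(out, "cliques") <- multi
  out
}
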