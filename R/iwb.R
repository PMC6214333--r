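#' Watershed markers: local maxima of local average coherence
#'
#' A vertex is a marker when its local average coherence (mean coherence
#' with its Voronoi neighbors, sub-threshold values included) is at least
#' that of every Voronoi neighbor. On plateaus — Voronoi-connected groups of
#' local maxima with equal value — only the smallest label of each
#' plateau-connected component is kept, so flooding starts from one marker
#' per plateau.
#'
#' @inheritParams ccb_detect
#' @return Sorted character vector of marker labels.
#' @examples
#' tbl <- table1_network()
#' detect_markers(tbl$network, tbl$adjacency) # "a" "f" "h"
#' @export
detect_markers <- function(network, adjacency) {
  lav <- local_average_coherence(network, adjacency)
  vals <- lav$values
  labels <- network$layout$label
  is_max <- vapply(labels, function(v) {
    nb <- adjacency$neighbors[[v]]
    length(nb) == 0L || all(vals[v] >= vals[nb])
  }, logical(1))
  cand <- labels[is_max]
  keep <- character(0)
  seen <- character(0)
  for (v in sort(cand)) {
    if (v %in% seen) next
    # plateau component: equal-valued local maxima reachable via adjacency
    comp <- v
    frontier <- v
    while (length(frontier)) {
      nxt <- unique(unlist(adjacency$neighbors[frontier], use.names = FALSE))
      nxt <- setdiff(intersect(nxt, cand), comp)
      nxt <- nxt[vals[nxt] == vals[v]]
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    keep <- c(keep, min(comp))
    seen <- c(seen, comp)
  }
  sort(keep)
}

#' Improved watershed based FU detection (IWB)
#'
#' Greedy flooding of the significant graph from the local-maximum markers of
#' [detect_markers()]. The edge queue starts with the significant edges
#' between each marker and its (unlabelled) Voronoi neighbors, sorted by
#' descending coherence (ties: insertion order, then lexicographic pair).
#' Repeatedly the maximal edge `(v, v')` is popped:
#'
#' * `v'` unlabelled and significantly connected to *every* member of the
#'   basin of `v`: `v'` joins that basin and the significant edges from `v'`
#'   to its unlabelled Voronoi neighbors are appended; if the clique
#'   condition fails the edge is discarded (not re-queued);
#' * `v'` labelled in a different basin: the two basins merge iff their
#'   union is a clique in the significant graph;
#' * otherwise nothing happens.
#'
#' When the queue is empty, each basin is an FU and unlabelled vertices
#' become singletons. Every basin is at all times a Voronoi-connected clique
#' of the significant graph.
#'
#' @inheritParams ccb_detect
#' @param trace also record the popped-edge sequence (attribute `trace`, a
#'   data frame with columns `v`, `v2`, `value`, `action`) where `action`
#'   is one of `"label"`, `"merge"`, `"merge_fail"`, `"noop"`, `"discard"`.
#' @return An [fu_partition()]; with `trace = TRUE` it carries the `trace`
#'   attribute and a `markers` attribute.
#' @examples
#' tbl <- table1_network()
#' iwb_detect(tbl$network, tbl$adjacency)
#' @export
iwb_detect <- function(network, adjacency, trace = FALSE) {
  stopifnot(inherits(network, "coherence_network"),
            inherits(adjacency, "voronoi_adjacency"))
  labels <- network$layout$label
  W <- network$coherence
  theta <- network$theta
  sig <- function(u, v) W[u, v] >= theta
  markers <- detect_markers(network, adjacency)
  lab <- stats::setNames(rep(NA_integer_, length(labels)), labels)
  lab[markers] <- seq_along(markers)
  basins <- as.list(markers)

  queue <- data.frame(v = character(0), v2 = character(0),
                      value = numeric(0), ins = integer(0),
                      stringsAsFactors = FALSE)
  ins_counter <- 0L
  push <- function(q, u, targets) {
    targets <- targets[is.na(lab[targets]) & W[u, targets] >= theta]
    if (length(targets) == 0L) return(q)
    add <- data.frame(v = u, v2 = targets, value = W[u, targets],
                      ins = ins_counter + seq_along(targets),
                      stringsAsFactors = FALSE)
    ins_counter <<- ins_counter + length(targets)
    rbind(q, add)
  }
  for (mk in markers) queue <- push(queue, mk, adjacency$neighbors[[mk]])

  tr <- list()
  while (nrow(queue) > 0L) {
    o <- order(-queue$value, queue$ins, queue$v, queue$v2)
    queue <- queue[o, , drop = FALSE]
    e <- queue[1L, ]
    queue <- queue[-1L, , drop = FALSE]
    v <- e$v; v2 <- e$v2
    action <- "noop"
    if (is.na(lab[v2])) {
      b <- lab[[v]]
      if (all(W[v2, basins[[b]]] >= theta)) {
        lab[v2] <- b
        basins[[b]] <- c(basins[[b]], v2)
        queue <- push(queue, v2, adjacency$neighbors[[v2]])
        action <- "label"
      } else {
        action <- "discard"
      }
    } else if (lab[[v2]] != lab[[v]]) {
      b1 <- lab[[v]]; b2 <- lab[[v2]]
      uni <- c(basins[[b1]], basins[[b2]])
      sub <- W[uni, uni]
      if (all(sub[upper.tri(sub)] >= theta)) {
        lab[basins[[b2]]] <- b1
        basins[[b1]] <- uni
        basins[[b2]] <- character(0)
        action <- "merge"
      } else {
        action <- "merge_fail"
      }
    }
    if (trace) {
      tr[[length(tr) + 1L]] <- data.frame(v = v, v2 = v2, value = e$value,
                                          action = action,
                                          stringsAsFactors = FALSE)
    }
  }
  sets <- c(basins[lengths(basins) > 0L], as.list(labels[is.na(lab)]))
  out <- fu_partition(sets, labels = labels)
  if (trace) {
    attr(out, "trace") <- do.call(rbind, tr)
    attr(out, "markers") <- markers
  }
  out
}
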