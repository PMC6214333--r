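#' Coherence networks
#'
#' A coherence network couples an electrode layout with a symmetric matrix of
#' magnitude-squared coherences `c(v, v')` in `[0, 1]` (zero diagonal:
#' electrodes are not self-connected) and a significance threshold `theta`.
#' Coherences at or above `theta` form the edges of the *significant graph*
#' on which FUs are detected; sub-threshold coherences are retained because
#' several summaries (local average coherence, within- and between-FU
#' coherence) average over *all* pairs.
#'
#' @param layout an [electrode_layout()].
#' @param coherence square numeric matrix, dimnames matching `layout$label`
#'   (unnamed matrices are taken to be in layout order). Must be symmetric
#'   to within `1e-12`, with zero diagonal and entries in `[0, 1]`.
#' @param theta significance threshold in `[0, 1]` (see
#'   [significance_threshold()] for the analytic choice).
#' @return An object of class `coherence_network`.
#' @export
coherence_network <- function(layout, coherence, theta) {
  stopifnot(inherits(layout, "electrode_layout"))
  n <- nrow(layout)
  coherence <- as.matrix(coherence)
  if (!is.numeric(coherence) || nrow(coherence) != n || ncol(coherence) != n) {
    stop("coherence must be a ", n, " x ", n, " numeric matrix")
  }
  if (!is.null(rownames(coherence))) {
    if (!setequal(rownames(coherence), layout$label) ||
        !identical(rownames(coherence), colnames(coherence))) {
      stop("coherence dimnames must match the layout labels")
    }
    coherence <- coherence[layout$label, layout$label]
  } else {
    dimnames(coherence) <- list(layout$label, layout$label)
  }
  if (max(abs(coherence - t(coherence))) > 1e-12) {
    stop("coherence matrix is not symmetric (tolerance 1e-12)")
  }
  if (any(diag(coherence) != 0)) {
    stop("coherence diagonal must be exactly 0 (no self-connections)")
  }
  if (any(coherence < 0) || any(coherence > 1)) {
    stop("coherence values must lie in [0, 1]")
  }
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta > 1) {
    stop("theta must be a single value in [0, 1]")
  }
  structure(list(layout = layout, coherence = coherence, theta = theta),
            class = "coherence_network")
}

#' @export
print.coherence_network <- function(x, ...) {
  nsig <- sum(x$coherence[upper.tri(x$coherence)] >= x$theta)
  cat("<coherence_network> ", nrow(x$layout), " electrodes, theta = ",
      format(x$theta), ", ", nsig, " significant edges\n", sep = "")
  invisible(x)
}

#' Analytic coherence significance threshold
#'
#' For coherence estimated by averaging over `L` independent segments, the
#' null (no true coherence) distribution of the estimate has
#' `P(c > x) = (1 - x)^(L - 1)`, so the `(1 - p)` null quantile is
#' `theta = 1 - p^(1 / (L - 1))`. Coherences at or above `theta` are deemed
#' significant at probability `p`.
#'
#' @param p tail probability in (0, 1) (e.g. `0.01`).
#' @param L number of averaged segments, an integer `>= 2` (the estimate from
#'   a single segment is identically 1, so the formula is undefined there).
#' @return The threshold `theta` in (0, 1).
#' @examples
#' significance_threshold(0.01, 13) # 0.3187...
#' @export
significance_threshold <- function(p, L) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    stop("p must be a single probability in (0, 1)")
  }
  if (!is.numeric(L) || length(L) != 1L || L < 2 || L != round(L)) {
    stop("L must be an integer >= 2")
  }
  1 - p^(1 / (L - 1))
}

#' Significant coherence graph
#'
#' Thresholds a coherence network into its weighted significant graph: an
#' edge is present iff `c(u, v) >= theta` (closed inequality), with the
#' coherence kept as edge weight.
#'
#' @param network a [coherence_network()].
#' @param theta optional override of the network's threshold.
#' @return An object of class `significant_graph`: a list with `labels`, the
#'   thresholded weight matrix `W` (sub-threshold entries zeroed), an edge
#'   data frame `edges` (`u`, `v`, `w`; `u < v`), and `theta`.
#' @export
significant_graph <- function(network, theta = network$theta) {
  stopifnot(inherits(network, "coherence_network"))
  W <- network$coherence
  W[W < theta] <- 0
  labels <- network$layout$label
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  edges <- data.frame(u = labels[idx[, 1]], v = labels[idx[, 2]],
                      w = W[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$u, edges$v), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(labels = labels, W = W, edges = edges, theta = theta),
            class = "significant_graph")
}

#' @export
print.significant_graph <- function(x, ...) {
  cat("<significant_graph> ", length(x$labels), " vertices, ",
      nrow(x$edges), " edges (theta = ", format(x$theta), ")\n", sep = "")
  invisible(x)
}

#' Local average coherence and vertex ordering
#'
#' The local average coherence of electrode `v` is the mean coherence
#' between `v` and its Voronoi neighbors, *including* sub-threshold
#' coherences. It orders the vertices for community clique detection and
#' defines the local-maximum markers of the watershed method.
#'
#' @param network a [coherence_network()].
#' @param adjacency a [voronoi_adjacency()] over the same layout.
#' @return A list with `values` (named numeric vector, layout order) and
#'   `order` (labels sorted by descending value, ties broken by ascending
#'   label).
#' @export
local_average_coherence <- function(network, adjacency) {
  stopifnot(inherits(network, "coherence_network"),
            inherits(adjacency, "voronoi_adjacency"))
  labels <- network$layout$label
  if (!identical(labels, adjacency$labels)) {
    stop("network and adjacency are over different layouts")
  }
  vals <- vapply(labels, function(v) {
    nb <- adjacency$neighbors[[v]]
    if (length(nb) == 0L) return(0)
    mean(network$coherence[v, nb])
  }, numeric(1))
  ord <- labels[order(-vals, labels)]
  list(values = vals, order = ord)
}

#' Read / write coherence matrix files
#'
#' Delimited text where the first row and first column hold electrode labels
#' and each cell holds the coherence between the row and column electrodes.
#' On read the matrix must be symmetric to within `1e-9`; it is then
#' symmetrized by averaging with its transpose and the diagonal forced to 0.
#'
#' @param path file path.
#' @param sep field separator.
#' @return `read_coherence_matrix()` returns a numeric matrix with label
#'   dimnames; `write_coherence_matrix()` returns `path` invisibly.
#' @export
read_coherence_matrix <- function(path, sep = ",") {
  if (!file.exists(path)) stop("coherence matrix file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df)
  if (nrow(M) != ncol(M) || !identical(rownames(M), colnames(M))) {
    stop("coherence matrix must be square with matching row/column labels: ", path)
  }
  if (max(abs(M - t(M))) > 1e-9) {
    stop("coherence matrix is not symmetric within 1e-9: ", path)
  }
  M <- (M + t(M)) / 2
  diag(M) <- 0
  M
}

#' @param M numeric matrix with label dimnames (e.g. `network$coherence`).
#' @rdname read_coherence_matrix
#' @export
write_coherence_matrix <- function(M, path, sep = ",") {
  df <- as.data.frame(M)
  utils::write.table(cbind(label = rownames(M), df), path, sep = sep,
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
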