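#' Voronoi spatial adjacency of an electrode layout
#'
#' The Voronoi diagram of the electrode positions partitions the plane into
#' cells of points sharing the same nearest electrode. Two electrodes are
#' *Voronoi neighbors* when their cells share a boundary segment of positive
#' length; this neighbor relation is the notion of spatial adjacency used by
#' all FU detection methods in this package.
#'
#' Cells are computed by half-plane clipping: the cell of electrode `u` is
#' the intersection of the half-planes of points at least as close to `u` as
#' to each other electrode, clipped to a large bounding box far outside the
#' layout (the box only truncates unbounded cells; it cannot create or
#' destroy a shared boundary between cells near the sites). Each polygon edge
#' remembers which electrode's bisector generated it, so adjacency is read
#' off directly from the final polygons. Four cocircular points (as at every
#' interior corner of a rectangular grid) meet in a single Voronoi vertex;
#' the diagonal pairs share only that point and are correctly *not* reported
#' as neighbors (`tol` separates true edges from such degenerate contacts).
#'
#' @param layout an [electrode_layout()] with at least 2 electrodes.
#' @param tol relative tolerance: shared boundaries shorter than
#'   `tol * diameter(layout)` are treated as degenerate point contacts.
#' @return An object of class `voronoi_adjacency`: a list with elements
#'   `labels`, `neighbors` (named list, each a sorted character vector) and
#'   `pairs` (two-column data frame of unordered neighbor pairs, `u < v`).
#' @examples
#' adj <- voronoi_adjacency(fixture_layout("fig3-grid"))
#' adj$neighbors$f  # "b" "e" "g" "j"
#' @export
voronoi_adjacency <- function(layout, tol = 1e-7) {
  stopifnot(inherits(layout, "electrode_layout"))
  n <- nrow(layout)
  if (n < 2L) stop("voronoi_adjacency needs at least 2 electrodes")
  pts <- cbind(layout$x, layout$y)
  labels <- layout$label
  scale <- max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1)
  eps <- tol * scale
  cells <- voronoi_cells_raw(pts)
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    v <- cells[[i]]$verts
    s <- cells[[i]]$src
    k <- nrow(v)
    if (k < 2L) next
    nxt <- c(seq_len(k)[-1L], 1L)
    len <- sqrt(rowSums((v[nxt, , drop = FALSE] - v)^2))
    js <- unique(s[s > 0L & len > eps])
    nb[[i]] <- js
  }
  # symmetrize: keep a pair only if seen from either side (clipping order can
  # leave a sliver on one side only in near-degenerate cases)
  mat <- matrix(FALSE, n, n)
  for (i in seq_len(n)) mat[i, nb[[i]]] <- TRUE
  mat <- mat | t(mat)
  diag(mat) <- FALSE
  neighbors <- lapply(seq_len(n), function(i) sort(labels[mat[i, ]]))
  names(neighbors) <- labels
  idx <- which(upper.tri(mat) & mat, arr.ind = TRUE)
  pairs <- data.frame(u = labels[idx[, 1]], v = labels[idx[, 2]],
                      stringsAsFactors = FALSE)
  ord <- order(pairs$u, pairs$v)
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(labels = labels, neighbors = neighbors, pairs = pairs),
            class = "voronoi_adjacency")
}

#' @export
print.voronoi_adjacency <- function(x, ...) {
  cat("<voronoi_adjacency> ", length(x$labels), " electrodes, ",
      nrow(x$pairs), " neighbor pairs\n", sep = "")
  invisible(x)
}

# Voronoi cells of a point set, clipped to a distant bounding box.
# Returns a list of list(verts = k x 2 matrix (counter-clockwise),
# src = integer vector: src[e] is the site index whose bisector generated the
# edge verts[e] -> verts[e+1], or 0 for a bounding-box edge.
voronoi_cells_raw <- function(pts) {
  n <- nrow(pts)
  cx <- mean(range(pts[, 1]))
  cy <- mean(range(pts[, 2]))
  half <- max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1) * 10
  box <- rbind(c(cx - half, cy - half), c(cx + half, cy - half),
               c(cx + half, cy + half), c(cx - half, cy + half))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    verts <- box
    src <- rep(0L, 4L)
    d2 <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2
    for (j in order(d2)) {
      if (j == i) next
      clipped <- clip_halfplane(verts, src, pts[i, ], pts[j, ], j)
      verts <- clipped$verts
      src <- clipped$src
      if (nrow(verts) == 0L) break
    }
    out[[i]] <- list(verts = verts, src = src)
  }
  out
}

# Sutherland-Hodgman clip of polygon (verts, edge sources src) by the
# half-plane of points at least as close to `a` as to `b`; edges created on
# the bisector get source `id`.
clip_halfplane <- function(verts, src, a, b, id) {
  k <- nrow(verts)
  if (k == 0L) return(list(verts = verts, src = src))
  d <- b - a
  m <- (a + b) / 2
  f <- (verts[, 1] - m[1]) * d[1] + (verts[, 2] - m[2]) * d[2]
  inside <- f <= 0
  if (all(inside)) return(list(verts = verts, src = src))
  if (!any(inside)) return(list(verts = verts[0, , drop = FALSE], src = integer(0)))
  ov <- matrix(0, 0, 2)
  os <- integer(0)
  for (e in seq_len(k)) {
    e2 <- if (e == k) 1L else e + 1L
    P <- verts[e, ]; Q <- verts[e2, ]
    if (inside[e]) {
      if (inside[e2]) {
        ov <- rbind(ov, P); os <- c(os, src[e])
      } else {
        t <- f[e] / (f[e] - f[e2])
        I <- P + t * (Q - P)
        ov <- rbind(ov, P, I)
        os <- c(os, src[e], id)
      }
    } else if (inside[e2]) {
      t <- f[e] / (f[e] - f[e2])
      I <- P + t * (Q - P)
      ov <- rbind(ov, I); os <- c(os, src[e])
    }
  }
  list(verts = ov, src = os)
}

#' Voronoi cell polygons for rendering
#'
#' Returns the Voronoi cell of every electrode clipped to a display boundary.
#' Clipping is purely cosmetic: spatial adjacency is always derived from the
#' unclipped (bounding-box) diagram via [voronoi_adjacency()].
#'
#' @param layout an [electrode_layout()].
#' @param boundary `"hull"` (padded convex hull of the electrode positions),
#'   `"circle"` (padded circumscribed circle, the usual head outline for
#'   scalp montages), or `"box"` (padded bounding box).
#' @param pad padding as a fraction of the layout diameter.
#' @return Named list (one entry per electrode) of k x 2 vertex matrices.
#' @export
voronoi_cells <- function(layout, boundary = c("hull", "circle", "box"),
                          pad = 0.25) {
  stopifnot(inherits(layout, "electrode_layout"))
  boundary <- match.arg(boundary)
  pts <- cbind(layout$x, layout$y)
  n <- nrow(pts)
  cx <- mean(range(pts[, 1])); cy <- mean(range(pts[, 2]))
  diam <- max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1)
  clip_poly <- switch(boundary,
    box = {
      hw <- diam / 2 * (1 + 2 * pad)
      hx <- diff(range(pts[, 1])) / 2 + pad * diam
      hy <- diff(range(pts[, 2])) / 2 + pad * diam
      rbind(c(cx - hx, cy - hy), c(cx + hx, cy - hy),
            c(cx + hx, cy + hy), c(cx - hx, cy + hy))
    },
    circle = {
      r <- max(sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2)) + pad * diam
      th <- seq(0, 2 * pi, length.out = 73L)[-73L]
      cbind(cx + r * cos(th), cy + r * sin(th))
    },
    hull = {
      h <- grDevices::chull(pts[, 1], pts[, 2])
      hp <- pts[h, , drop = FALSE]
      # chull returns clockwise order; expand outward from the centroid
      ctr <- colMeans(hp)
      expand <- hp + pad * diam * t(apply(hp, 1, function(p) {
        d <- p - ctr; nr <- sqrt(sum(d^2)); if (nr == 0) c(0, 0) else d / nr
      }))
      # ensure counter-clockwise orientation for clipping
      area2 <- sum(expand[, 1] * expand[c(2:nrow(expand), 1), 2] -
                   expand[c(2:nrow(expand), 1), 1] * expand[, 2])
      if (area2 < 0) expand <- expand[rev(seq_len(nrow(expand))), , drop = FALSE]
      expand
    })
  if (n == 1L) {
    out <- list(clip_poly)
    names(out) <- layout$label
    return(out)
  }
  cells <- voronoi_cells_raw(pts)
  out <- lapply(seq_len(n), function(i) {
    v <- cells[[i]]$verts
    s <- cells[[i]]$src
    clip_to_polygon(v, s, clip_poly)$verts
  })
  names(out) <- layout$label
  out
}

# clip a polygon to a convex counter-clockwise polygon via repeated
# half-plane clipping (edge normals point outward; inside is f <= 0)
clip_to_polygon <- function(verts, src, poly) {
  k <- nrow(poly)
  for (e in seq_len(k)) {
    e2 <- if (e == k) 1L else e + 1L
    p1 <- poly[e, ]; p2 <- poly[e2, ]
    edge <- p2 - p1
    nrm <- c(edge[2], -edge[1]) # outward for CCW polygon
    # reuse clip_halfplane by constructing fake sites: keep (x - p1) . nrm <= 0
    kk <- nrow(verts)
    if (kk == 0L) break
    f <- (verts[, 1] - p1[1]) * nrm[1] + (verts[, 2] - p1[2]) * nrm[2]
    res <- clip_by_values(verts, src, f, 0L)
    verts <- res$verts; src <- res$src
  }
  list(verts = verts, src = src)
}

# shared Sutherland-Hodgman core given precomputed signed values f
clip_by_values <- function(verts, src, f, id) {
  k <- nrow(verts)
  inside <- f <= 0
  if (all(inside)) return(list(verts = verts, src = src))
  if (!any(inside)) return(list(verts = verts[0, , drop = FALSE], src = integer(0)))
  ov <- matrix(0, 0, 2); os <- integer(0)
  for (e in seq_len(k)) {
    e2 <- if (e == k) 1L else e + 1L
    P <- verts[e, ]; Q <- verts[e2, ]
    if (inside[e]) {
      if (inside[e2]) {
        ov <- rbind(ov, P); os <- c(os, src[e])
      } else {
        t <- f[e] / (f[e] - f[e2])
        ov <- rbind(ov, P, P + t * (Q - P)); os <- c(os, src[e], id)
      }
    } else if (inside[e2]) {
      t <- f[e] / (f[e] - f[e2])
      ov <- rbind(ov, P + t * (Q - P)); os <- c(os, src[e])
    }
  }
  list(verts = ov, src = os)
}

#' Is a set of electrodes Voronoi-connected?
#'
#' A set is Voronoi-connected when it is empty, a singleton, or induces a
#' connected subgraph of the Voronoi neighbor relation. Every FU produced by
#' the detection methods satisfies this property.
#'
#' @param members character vector of electrode labels (may be empty).
#' @param adjacency a [voronoi_adjacency()].
#' @return `TRUE` or `FALSE`.
#' @export
is_voronoi_connected <- function(members, adjacency) {
  stopifnot(inherits(adjacency, "voronoi_adjacency"))
  members <- as.character(members)
  unknown <- setdiff(members, adjacency$labels)
  if (length(unknown)) {
    stop("unknown electrode labels: ", paste(unknown, collapse = ", "))
  }
  if (length(members) <= 1L) return(TRUE)
  inset <- members
  seen <- members[1L]
  frontier <- seen
  while (length(frontier)) {
    nxt <- unique(unlist(adjacency$neighbors[frontier], use.names = FALSE))
    nxt <- setdiff(intersect(nxt, inset), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(members)
}

# fast internal variant on a logical adjacency matrix with integer indices
vor_connected_idx <- function(idx, amat) {
  k <- length(idx)
  if (k <= 1L) return(TRUE)
  seen <- logical(nrow(amat))
  seen[idx[1L]] <- TRUE
  frontier <- idx[1L]
  inset <- logical(nrow(amat))
  inset[idx] <- TRUE
  while (length(frontier)) {
    nxt <- which(matrixOr(amat, frontier) & inset & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  sum(seen) == k
}

matrixOr <- function(amat, rows) {
  if (length(rows) == 1L) amat[rows, ] else colSums(amat[rows, , drop = FALSE]) > 0
}
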