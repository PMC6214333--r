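#' Average within-FU coherence
#'
#' The mean coherence over all ordered pairs of distinct members,
#' `sum c(v_i, v_j) / (|C| (|C| - 1))`, *including* sub-threshold
#' coherences. Undefined for fewer than two members (`NA`, rendered as an
#' uncolored circle).
#'
#' @param members character vector of electrode labels.
#' @param network a [coherence_network()].
#' @return The average coherence in `[0, 1]`, or `NA` for `|C| < 2`.
#' @examples
#' tbl <- table1_network()
#' average_coherence(c("d", "h", "l"), tbl$network) # 0.71
#' @export
average_coherence <- function(members, network) {
  stopifnot(inherits(network, "coherence_network"))
  members <- as.character(members)
  unknown <- setdiff(members, network$layout$label)
  if (length(unknown)) stop("unknown labels: ", paste(unknown, collapse = ", "))
  k <- length(members)
  if (k < 2L) return(NA_real_)
  sum(network$coherence[members, members]) / (k * (k - 1L))
}

#' Inter-FU coherence
#'
#' The summed coherence between the two member sets divided by the maximal
#' number of edges between them, `sum c(v_i, v_j) / (|C1| |C2|)`, with
#' coherences between *any* pair counted (sub-threshold included) so that
#' the value is normalized for FU size. Symmetric in its arguments.
#'
#' @param C1,C2 disjoint non-empty character vectors of electrode labels.
#' @param network a [coherence_network()].
#' @return The inter-FU coherence in `[0, 1]`.
#' @export
inter_fu_coherence <- function(C1, C2, network) {
  stopifnot(inherits(network, "coherence_network"))
  C1 <- as.character(C1); C2 <- as.character(C2)
  if (length(C1) == 0L || length(C2) == 0L) stop("FUs must be non-empty")
  unknown <- setdiff(c(C1, C2), network$layout$label)
  if (length(unknown)) stop("unknown labels: ", paste(unknown, collapse = ", "))
  if (length(intersect(C1, C2))) {
    stop("FUs overlap: ", paste(intersect(C1, C2), collapse = ", "))
  }
  sum(network$coherence[C1, C2, drop = FALSE]) / (length(C1) * length(C2))
}

#' Per-FU summary table
#'
#' @param partition an [fu_partition()].
#' @param network a [coherence_network()].
#' @return A data frame with one row per FU: `fu`, `size`, `members`,
#'   `avg_coherence` ([average_coherence()], `NA` for singletons),
#'   `total_strength` ([total_strength()]), and barycenter `bx`, `by`.
#' @export
fu_summary <- function(partition, network) {
  stopifnot(inherits(partition, "fu_partition"),
            inherits(network, "coherence_network"))
  graph <- significant_graph(network)
  lay <- network$layout
  rows <- lapply(seq_along(partition$communities), function(i) {
    s <- partition$communities[[i]]
    sel <- match(s, lay$label)
    data.frame(fu = i, size = length(s), members = paste(s, collapse = " "),
               avg_coherence = average_coherence(s, network),
               total_strength = total_strength(s, graph),
               bx = mean(lay$x[sel]), by = mean(lay$y[sel]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise inter-FU coherence table
#'
#' @inheritParams fu_summary
#' @return Data frame with columns `fu1`, `fu2`, `coherence` for all
#'   unordered FU pairs (empty when the partition has fewer than two FUs).
#' @export
inter_fu_table <- function(partition, network) {
  k <- length(partition$communities)
  if (k < 2L) {
    return(data.frame(fu1 = integer(0), fu2 = integer(0),
                      coherence = numeric(0)))
  }
  pairs <- utils::combn(k, 2L)
  data.frame(
    fu1 = pairs[1, ], fu2 = pairs[2, ],
    coherence = apply(pairs, 2, function(p) {
      inter_fu_coherence(partition$communities[[p[1]]],
                         partition$communities[[p[2]]], network)
    }))
}

# fixed sequential color map with [0, 1] domain so colors are comparable
# across maps
coherence_color <- function(v) {
  pal <- grDevices::hcl.colors(256L, "viridis")
  pal[pmin(pmax(floor(v * 255) + 1L, 1L), 256L)]
}

#' Build an FU-map specification
#'
#' Assembles everything needed to draw an FU map: the Voronoi cell polygon of
#' every electrode (clipped to a display boundary), a gray level per
#' *displayed* FU (size `>= display_min_size`) chosen greedily so that
#' Voronoi-adjacent displayed FUs never share a gray, white cells for smaller
#' FUs, a circle at each displayed FU's barycenter colored by its average
#' coherence, and a line between displayed FU barycenters whose inter-FU
#' coherence reaches `line_threshold`, colored by that coherence.
#'
#' @param partition an [fu_partition()].
#' @param network a [coherence_network()].
#' @param display_min_size smallest FU size that gets a gray level, a circle
#'   and lines (default 5).
#' @param line_threshold inter-FU coherence needed for a line; defaults to
#'   the network's significance threshold.
#' @param strict_lines if `TRUE`, lines require coherence strictly above the
#'   threshold instead of the default closed comparison.
#' @param boundary display boundary passed to [voronoi_cells()].
#' @return An object of class `fu_map_spec`.
#' @export
build_fu_map <- function(partition, network, display_min_size = 5L,
                         line_threshold = network$theta,
                         strict_lines = FALSE,
                         boundary = c("hull", "circle", "box")) {
  stopifnot(inherits(partition, "fu_partition"),
            inherits(network, "coherence_network"))
  boundary <- match.arg(boundary)
  lay <- network$layout
  if (!setequal(names(partition$membership), lay$label)) {
    stop("partition does not cover the network's layout")
  }
  adjacency <- voronoi_adjacency(lay)
  cells <- voronoi_cells(lay, boundary = boundary)
  k <- length(partition$communities)
  sizes <- lengths(partition$communities)
  displayed <- which(sizes >= display_min_size)

  # FU adjacency: any Voronoi-adjacent electrode pair across two FUs
  fu_adj <- matrix(FALSE, k, k)
  mem <- partition$membership
  for (r in seq_len(nrow(adjacency$pairs))) {
    i <- mem[[adjacency$pairs$u[r]]]
    j <- mem[[adjacency$pairs$v[r]]]
    if (i != j) {
      fu_adj[i, j] <- TRUE
      fu_adj[j, i] <- TRUE
    }
  }
  # greedy gray coloring of displayed FUs over an ordered gray palette
  ngr <- max(4L, length(displayed))
  palette <- grDevices::gray(seq(0.40, 0.85, length.out = ngr))
  gray <- rep(NA_character_, k)
  for (i in displayed) {
    used <- gray[displayed[fu_adj[i, displayed]]]
    gray[i] <- setdiff(palette, used)[1L]
  }

  summ <- fu_summary(partition, network)
  circles <- summ[summ$fu %in% displayed, , drop = FALSE]
  circles$color <- ifelse(is.na(circles$avg_coherence), NA_character_,
                          coherence_color(circles$avg_coherence))
  inter <- inter_fu_table(partition, network)
  inter <- inter[inter$fu1 %in% displayed & inter$fu2 %in% displayed, ,
                 drop = FALSE]
  keep <- if (strict_lines) inter$coherence > line_threshold else
    inter$coherence >= line_threshold
  lines <- inter[keep, , drop = FALSE]
  if (nrow(lines)) {
    lines$x1 <- summ$bx[lines$fu1]; lines$y1 <- summ$by[lines$fu1]
    lines$x2 <- summ$bx[lines$fu2]; lines$y2 <- summ$by[lines$fu2]
    lines$color <- coherence_color(lines$coherence)
  }
  structure(list(layout = lay, cells = cells, membership = mem,
                 communities = partition$communities, gray = gray,
                 displayed = displayed, circles = circles, lines = lines,
                 display_min_size = display_min_size,
                 line_threshold = line_threshold,
                 color_scale = "sequential viridis, domain [0, 1]"),
            class = "fu_map_spec")
}

#' @export
print.fu_map_spec <- function(x, ...) {
  cat("<fu_map_spec> ", length(x$cells), " cells, ", length(x$displayed),
      " displayed FUs, ", if (is.null(x$lines)) 0L else nrow(x$lines),
      " inter-FU lines\n", sep = "")
  invisible(x)
}

#' Render an FU map to SVG or PNG
#'
#' Top view, nose up. White cells belong to FUs below the display size;
#' displayed FUs get their assigned gray, a barycenter circle colored by
#' average coherence, and lines colored by inter-FU coherence; a vertical
#' color bar shows the fixed `[0, 1]` scale. SVG output is plain text and
#' byte-stable for fixed inputs.
#'
#' @param spec an [build_fu_map()] result.
#' @param path output file path.
#' @param format `"svg"` or `"png"`.
#' @param width image width in pixels.
#' @return `path`, invisibly.
#' @export
render_fu_map <- function(spec, path, format = c("svg", "png"), width = 640) {
  stopifnot(inherits(spec, "fu_map_spec"))
  format <- match.arg(format)
  if (format == "svg") {
    writeLines(fu_map_svg(spec, width), path, useBytes = TRUE)
  } else {
    render_fu_map_png(spec, path, width)
  }
  invisible(path)
}

fu_map_svg <- function(spec, width = 640) {
  allv <- do.call(rbind, spec$cells)
  xr <- range(allv[, 1]); yr <- range(allv[, 2])
  pad <- 0.05 * max(diff(xr), diff(yr))
  xr <- xr + c(-pad, pad); yr <- yr + c(-pad, pad)
  sc <- (width - 80) / diff(xr) # leave room for the color bar
  height <- round(diff(yr) * sc) + 20
  tx <- function(x) sprintf("%.2f", (x - xr[1]) * sc + 10)
  ty <- function(y) sprintf("%.2f", (yr[2] - y) * sc + 10) # nose up: +y on top
  out <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d"',
                          ' height="%d" viewBox="0 0 %d %d">'),
                   width, height, width, height),
           '<rect width="100%" height="100%" fill="white"/>')
  r_mark <- 0.012 * width
  for (i in seq_along(spec$cells)) {
    v <- spec$cells[[i]]
    if (nrow(v) < 3L) next
    fu <- spec$membership[[names(spec$cells)[i]]]
    fill <- if (is.na(spec$gray[fu])) "white" else spec$gray[fu]
    pts <- paste(paste0(tx(v[, 1]), ",", ty(v[, 2])), collapse = " ")
    out <- c(out, sprintf(
      '<polygon points="%s" fill="%s" stroke="black" stroke-width="0.8"/>',
      pts, fill))
  }
  if (!is.null(spec$lines) && nrow(spec$lines)) {
    for (r in seq_len(nrow(spec$lines))) {
      l <- spec$lines[r, ]
      out <- c(out, sprintf(
        '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="3"/>',
        tx(l$x1), ty(l$y1), tx(l$x2), ty(l$y2), l$color))
    }
  }
  if (nrow(spec$circles)) {
    for (r in seq_len(nrow(spec$circles))) {
      ci <- spec$circles[r, ]
      fill <- if (is.na(ci$color)) "none" else ci$color
      out <- c(out, sprintf(
        '<circle cx="%s" cy="%s" r="%.2f" fill="%s" stroke="black"/>',
        tx(ci$bx), ty(ci$by), r_mark, fill))
    }
  }
  # electrode label dots
  for (i in seq_len(nrow(spec$layout))) {
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-size="%.1f" text-anchor="middle">%s</text>',
      tx(spec$layout$x[i]), ty(spec$layout$y[i]), 0.022 * width,
      spec$layout$label[i]))
  }
  # color bar, fixed [0, 1] domain
  bar_x <- width - 50
  nstep <- 32L
  bh <- (height - 60) / nstep
  for (s in seq_len(nstep)) {
    v <- (s - 0.5) / nstep
    out <- c(out, sprintf(
      '<rect x="%d" y="%.2f" width="16" height="%.2f" fill="%s"/>',
      bar_x, 30 + (nstep - s) * bh, bh + 0.5, coherence_color(v)))
  }
  out <- c(out,
           sprintf('<text x="%d" y="%d" font-size="11">1.0</text>', bar_x + 20, 36),
           sprintf('<text x="%d" y="%d" font-size="11">0.0</text>',
                   bar_x + 20, round(30 + nstep * bh)),
           "</svg>")
  out
}

render_fu_map_png <- function(spec, path, width) {
  allv <- do.call(rbind, spec$cells)
  xr <- range(allv[, 1]); yr <- range(allv[, 2])
  grDevices::png(path, width = width, height = round(width * diff(yr) / diff(xr)))
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(1, 1, 1, 4))
  graphics::plot(NA, xlim = xr, ylim = yr, asp = 1, axes = FALSE,
                 xlab = "", ylab = "")
  for (i in seq_along(spec$cells)) {
    v <- spec$cells[[i]]
    if (nrow(v) < 3L) next
    fu <- spec$membership[[names(spec$cells)[i]]]
    fill <- if (is.na(spec$gray[fu])) "white" else spec$gray[fu]
    graphics::polygon(v[, 1], v[, 2], col = fill, border = "black")
  }
  if (!is.null(spec$lines) && nrow(spec$lines)) {
    graphics::segments(spec$lines$x1, spec$lines$y1, spec$lines$x2,
                       spec$lines$y2, col = spec$lines$color, lwd = 3)
  }
  if (nrow(spec$circles)) {
    graphics::points(spec$circles$bx, spec$circles$by, pch = 21,
                     bg = ifelse(is.na(spec$circles$color), "white",
                                 spec$circles$color), cex = 2)
  }
  graphics::text(spec$layout$x, spec$layout$y, spec$layout$label, cex = 0.8)
  invisible(path)
}

#' Dump an FU-map specification as JSON
#'
#' @param spec an [build_fu_map()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fu_map_json <- function(spec, path) {
  stopifnot(inherits(spec, "fu_map_spec"))
  obj <- list(
    cells = lapply(spec$cells, function(v) unname(apply(v, 1, c, simplify = FALSE))),
    membership = as.list(spec$membership),
    gray = spec$gray,
    displayed = spec$displayed,
    circles = spec$circles,
    lines = spec$lines,
    display_min_size = spec$display_min_size,
    line_threshold = spec$line_threshold,
    color_scale = spec$color_scale)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
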