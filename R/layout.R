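#' Electrode layouts
#'
#' An electrode layout is the top-view 2D projection of scalp electrode
#' positions: a set of unique labels with pairwise distinct planar
#' coordinates. It is the vertex set of every coherence network and the
#' point set of the Voronoi diagram that defines spatial adjacency.
#'
#' @param labels character vector of unique electrode identifiers.
#' @param x,y numeric coordinates (arbitrary planar units).
#' @return An object of class `electrode_layout`: a data frame with columns
#'   `label`, `x`, `y`.
#' @examples
#' lay <- electrode_layout(c("A", "B", "C"), x = c(0, 1, 2), y = c(0, 0, 1))
#' @export
electrode_layout <- function(labels, x, y) {
  labels <- as.character(labels)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(labels) < 1L) stop("layout needs at least one electrode")
  if (length(x) != length(labels) || length(y) != length(labels)) {
    stop("labels, x and y must have equal length")
  }
  if (anyDuplicated(labels)) {
    stop("duplicate electrode labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("electrode positions must be finite")
  }
  key <- paste(x, y)
  if (anyDuplicated(key)) {
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    stop("duplicate electrode positions for labels: ",
         paste(labels[dup], collapse = ", "))
  }
  out <- data.frame(label = labels, x = x, y = y, stringsAsFactors = FALSE)
  class(out) <- c("electrode_layout", "data.frame")
  out
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat("<electrode_layout> ", nrow(x), " electrodes\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Built-in electrode layouts
#'
#' * `"fig3-grid"`: a 3 x 4 rectangular grid with labels `a`..`l` laid out in
#'   rows `a b c d` / `e f g h` / `i j k l`; the label at row r (0 = top) and
#'   column k sits at (k, -r). On this unit grid, Voronoi adjacency equals
#'   4-connectivity. This is the layout of the built-in 12-node worked
#'   example (see [table1_network()]).
#' * `"montage-10-20"`: an approximate top-view 2D projection of the 19
#'   standard 10-20 electrode sites (nose up). Positions are schematic,
#'   intended for rendering and simulation, not for source analysis.
#'
#' @param name fixture name, one of `"fig3-grid"`, `"montage-10-20"`.
#' @return An [electrode_layout()].
#' @export
fixture_layout <- function(name = c("fig3-grid", "montage-10-20")) {
  name <- match.arg(name)
  if (name == "fig3-grid") {
    return(grid_layout(3L, 4L))
  }
  # Approximate 10-20 positions: unit head circle, nose up (+y anterior).
  pos <- rbind(
    Fp1 = c(-0.31, 0.95), Fp2 = c(0.31, 0.95),
    F7  = c(-0.81, 0.59), F3  = c(-0.42, 0.50), Fz = c(0.00, 0.50),
    F4  = c(0.42, 0.50),  F8  = c(0.81, 0.59),
    T3  = c(-1.00, 0.00), C3  = c(-0.50, 0.00), Cz = c(0.00, 0.00),
    C4  = c(0.50, 0.00),  T4  = c(1.00, 0.00),
    T5  = c(-0.81, -0.59), P3 = c(-0.42, -0.50), Pz = c(0.00, -0.50),
    P4  = c(0.42, -0.50), T6  = c(0.81, -0.59),
    O1  = c(-0.31, -0.95), O2 = c(0.31, -0.95)
  )
  electrode_layout(rownames(pos), pos[, 1], pos[, 2])
}

#' Rectangular grid layout
#'
#' Labels are assigned row-major from `letters` (then `a1`, `b1`, ... if more
#' than 26 cells are needed); the cell at row r (0 = top), column k gets
#' position (k, -r), so on this unit grid Voronoi neighbors are exactly the
#' 4-connected cells.
#'
#' @param rows,cols grid dimensions.
#' @return An [electrode_layout()].
#' @export
grid_layout <- function(rows, cols) {
  n <- rows * cols
  base <- letters
  if (n > length(base)) {
    reps <- ceiling(n / length(base))
    base <- paste0(rep(letters, reps), rep(c("", seq_len(reps - 1L)), each = 26L))
  }
  labels <- base[seq_len(n)]
  r <- rep(seq_len(rows) - 1L, each = cols)
  k <- rep(seq_len(cols) - 1L, times = rows)
  electrode_layout(labels, x = k, y = -r)
}

#' Read / write electrode layout files
#'
#' Delimited text with header `label,x,y`, one row per electrode, UTF-8.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return `read_layout()` returns an [electrode_layout()];
#'   `write_layout()` returns `path` invisibly.
#' @export
read_layout <- function(path, sep = ",") {
  if (!file.exists(path)) stop("layout file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("label", "x", "y")
  if (!all(need %in% names(df))) {
    stop("layout file must have columns label,x,y: ", path)
  }
  electrode_layout(df$label, df$x, df$y)
}

#' @param layout an [electrode_layout()].
#' @rdname read_layout
#' @export
write_layout <- function(layout, path, sep = ",") {
  utils::write.table(as.data.frame(layout)[, c("label", "x", "y")], path,
                     sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
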