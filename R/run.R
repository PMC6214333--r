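#' Run configuration
#'
#' Bundles everything one detection run needs. Exactly one of `theta` or the
#' pair (`p`, `L`) must determine the significance threshold; an explicit
#' `theta` takes precedence and both are recorded in the run manifest.
#'
#' @param method `"ccb"`, `"mcb"` or `"iwb"`.
#' @param theta explicit significance threshold, or `NULL` to derive it from
#'   `p` and `L` via [significance_threshold()].
#' @param p,L probability and segment count for the analytic threshold.
#' @param fixture built-in input name (`"table1"`) or `NULL` to read files.
#' @param layout_path,matrix_path input files (ignored when `fixture` set).
#' @param band frequency band in Hz (used by the coherence stage).
#' @param display_min_size,line_threshold,strict_lines FU-map parameters
#'   (see [build_fu_map()]).
#' @param seed integer seed for any randomized tie-breaking or simulation.
#' @param out_prefix path prefix for output files.
#' @return A list of class `run_config`.
#' @export
run_config <- function(method = c("ccb", "mcb", "iwb"), theta = NULL,
                       p = 0.01, L = 13L, fixture = NULL,
                       layout_path = NULL, matrix_path = NULL,
                       band = NULL, display_min_size = 5L,
                       line_threshold = NULL, strict_lines = FALSE,
                       seed = 1L, out_prefix = "eegfu") {
  method <- match.arg(method)
  theta_source <- if (is.null(theta)) "derived" else "explicit"
  if (is.null(theta)) theta <- significance_threshold(p, L)
  structure(list(method = method, theta = theta, theta_source = theta_source,
                 p = p, L = L,
                 fixture = fixture, layout_path = layout_path,
                 matrix_path = matrix_path, band = band,
                 display_min_size = display_min_size,
                 line_threshold = if (is.null(line_threshold)) theta else line_threshold,
                 strict_lines = strict_lines, seed = seed,
                 out_prefix = out_prefix),
            class = "run_config")
}

load_run_inputs <- function(config) {
  if (!is.null(config$fixture)) {
    fx <- fixture_network(config$fixture)
    net <- fx$network
    # built-in fixtures carry their own threshold; only an explicit theta
    # overrides it
    if (identical(config$theta_source, "explicit") &&
        config$theta != net$theta) {
      net <- coherence_network(net$layout, net$coherence, config$theta)
    }
    return(list(network = net, adjacency = fx$adjacency))
  }
  if (is.null(config$layout_path) || is.null(config$matrix_path)) {
    stop("either a fixture or both layout_path and matrix_path are required")
  }
  layout <- read_layout(config$layout_path)
  M <- read_coherence_matrix(config$matrix_path)
  diffset <- c(setdiff(layout$label, rownames(M)),
               setdiff(rownames(M), layout$label))
  if (length(diffset)) {
    stop("layout and matrix labels differ: ", paste(diffset, collapse = ", "))
  }
  network <- coherence_network(layout, M[layout$label, layout$label],
                               config$theta)
  list(network = network, adjacency = voronoi_adjacency(layout))
}

#' Run FU detection from a configuration
#'
#' Loads the inputs named by the configuration, runs the selected detection
#' method, and writes the partition (`<prefix>_partition.csv` and `.json`),
#' the FU summary and inter-FU tables (`<prefix>_summary.csv`,
#' `<prefix>_interfu.csv`) and a JSON run manifest recording the package
#' version, configuration and the threshold actually used.
#'
#' @param config a [run_config()].
#' @param write write output files (set `FALSE` to only return results).
#' @return Invisibly, a list with `partition`, `summary`, `interfu`,
#'   `network` and the manifest.
#' @export
run_detect <- function(config, write = TRUE) {
  stopifnot(inherits(config, "run_config"))
  inputs <- load_run_inputs(config)
  net <- inputs$network
  adj <- inputs$adjacency
  part <- switch(config$method,
                 ccb = ccb_detect(net, adj),
                 mcb = mcb_detect(net, adj),
                 iwb = iwb_detect(net, adj))
  summ <- fu_summary(part, net)
  inter <- inter_fu_table(part, net)
  manifest <- list(package = "eegfu",
                   version = as.character(utils::packageVersion("eegfu")),
                   method = config$method, theta = net$theta,
                   p = config$p, L = config$L, seed = config$seed,
                   fixture = config$fixture,
                   n_fus = length(part$communities),
                   n_multi_fus = sum(lengths(part$communities) > 1L))
  if (write) {
    pre <- config$out_prefix
    write_partition(part, paste0(pre, "_partition.csv"))
    write_partition(part, paste0(pre, "_partition.json"))
    utils::write.table(summ, paste0(pre, "_summary.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(inter, paste0(pre, "_interfu.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, paste0(pre, "_manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(list(partition = part, summary = summ, interfu = inter,
                 network = net, manifest = manifest))
}

#' Render an FU map from a configuration
#'
#' Runs [run_detect()] (without writing its files), builds the FU map and
#' renders it.
#'
#' @param config a [run_config()].
#' @param path output image path; extension selects the format unless
#'   `format` is given.
#' @param format `"svg"` or `"png"`; default follows the extension.
#' @return Invisibly, the [build_fu_map()] spec (with attribute `counts`).
#' @export
run_fumap <- function(config, path, format = NULL) {
  res <- run_detect(config, write = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.png$", path, ignore.case = TRUE)) "png" else "svg"
  }
  spec <- build_fu_map(res$partition, res$network,
                       display_min_size = config$display_min_size,
                       line_threshold = config$line_threshold,
                       strict_lines = config$strict_lines)
  render_fu_map(spec, path, format = format)
  attr(spec, "counts") <- c(displayed = length(spec$displayed),
                            lines = if (is.null(spec$lines)) 0L else nrow(spec$lines))
  message("FU map: ", length(spec$displayed), " displayed FUs, ",
          if (is.null(spec$lines)) 0L else nrow(spec$lines),
          " inter-FU lines -> ", path)
  invisible(spec)
}
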