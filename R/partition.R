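#' FU partitions
#'
#' A partition assigns every electrode to exactly one functional unit (FU).
#' The canonical form sorts members within each FU by label and numbers FUs
#' `1..k` by their smallest member label, so two partitions are equal iff
#' their canonical forms are identical — community detection output is only
#' defined up to relabeling.
#'
#' @param membership named integer (or character) vector mapping electrode
#'   label to community id, or a list of character vectors (the member sets).
#' @param labels optional full label set; labels absent from `membership`
#'   become singletons.
#' @return An object of class `fu_partition`: list with `membership` (named
#'   integer vector) and `communities` (list of sorted character vectors,
#'   indexed by canonical id).
#' @export
fu_partition <- function(membership, labels = NULL) {
  if (is.list(membership)) {
    sets <- lapply(unname(membership), as.character)
    mem <- unlist(lapply(seq_along(sets), function(i) {
      stats::setNames(rep(i, length(sets[[i]])), sets[[i]])
    }))
  } else {
    mem <- membership
  }
  if (is.null(names(mem))) stop("membership must be named by electrode label")
  if (anyDuplicated(names(mem))) stop("electrode assigned to multiple FUs")
  ids <- as.integer(factor(mem))
  names(ids) <- names(mem)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    extra <- setdiff(labels, names(ids))
    if (length(extra)) {
      ids <- c(ids, stats::setNames(max(ids, 0L) + seq_along(extra), extra))
    }
    ids <- ids[labels]
  }
  canonicalize_partition(ids)
}

canonicalize_partition <- function(ids) {
  sets <- split(names(ids), ids)
  sets <- lapply(sets, sort)
  sets <- sets[lengths(sets) > 0L]
  ord <- order(vapply(sets, `[`, character(1), 1L))
  sets <- unname(sets[ord])
  mem <- integer(length(ids))
  names(mem) <- names(ids)
  for (i in seq_along(sets)) mem[sets[[i]]] <- i
  structure(list(membership = mem, communities = sets), class = "fu_partition")
}

#' @export
print.fu_partition <- function(x, ...) {
  k <- length(x$communities)
  multi <- sum(lengths(x$communities) > 1L)
  cat("<fu_partition> ", k, " FUs (", multi, " with >1 electrode)\n", sep = "")
  for (i in seq_len(k)) {
    cat("  FU ", i, ": {", paste(x$communities[[i]], collapse = ", "), "}\n",
        sep = "")
  }
  invisible(x)
}

#' @export
format.fu_partition <- function(x, ...) {
  paste(vapply(x$communities, function(s) paste0("{", paste(s, collapse = ","), "}"),
               character(1)), collapse = " ")
}

#' Test two partitions for equality up to relabeling
#'
#' @param a,b `fu_partition` objects.
#' @return `TRUE` if the canonical member sets are identical.
#' @export
same_partition <- function(a, b) {
  identical(a$communities, b$communities)
}

#' Read / write FU partition files
#'
#' Two formats are supported: delimited text with header `label,community`
#' and JSON mapping community id to the sorted member label list. Community
#' ids are canonical (numbered by smallest member label).
#'
#' @param partition an `fu_partition`.
#' @param path output path; format chosen by extension (`.json` for JSON,
#'   anything else is delimited text).
#' @return `read_partition()` returns an `fu_partition`; `write_partition()`
#'   returns `path` invisibly.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "fu_partition"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- stats::setNames(partition$communities,
                           as.character(seq_along(partition$communities)))
    jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE)
  } else {
    df <- data.frame(label = names(partition$membership),
                     community = unname(partition$membership))
    df <- df[order(df$label), , drop = FALSE]
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop("partition file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(fu_partition(unname(as.list(obj))))
  }
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE)
  fu_partition(stats::setNames(df$community, df$label))
}
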