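#' Read an interaction table into a protein graph
#'
#' Parses a STRING-actions-style interaction table with columns
#' `(id_a, id_b, mode)` into a [protein_graph()].  The separator (tab or
#' comma) and the presence of a header line are detected from the first
#' line.  Proteins are indexed in order of first appearance.  Rows with
#' the same unordered pair are merged: their modes are OR-ed into a
#' single multi-label row, so `(A,B,binding)` plus `(B,A,activation)`
#' yields one edge labelled Binding and Activation.  Self-interaction
#' rows are skipped with a warning; an unknown mode string is a hard
#' error naming the offending line.
#'
#' @param path Path to the interaction file.
#' @param categories A [category_space()]; mode strings are matched
#'   case-insensitively against its names.
#' @return A [protein_graph()] without features.
#' @export
read_interactions <- function(path, categories = category_space()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no interactions parsed from ", path)
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("line ", bad[[1L]], " has fewer than 3 fields")
  first_mode <- match_category(fields[[1L]][[3L]], categories)
  header <- is.na(first_mode)
  start <- if (header) 2L else 1L
  if (start > length(lines)) stop("no interactions parsed from ", path)
  rows <- fields[seq.int(start, length(fields))]
  id_a <- trimws(vapply(rows, `[[`, "", 1L))
  id_b <- trimws(vapply(rows, `[[`, "", 2L))
  mode <- vapply(rows, `[[`, "", 3L)
  cat_idx <- match_category(mode, categories)
  if (anyNA(cat_idx)) {
    off <- which(is.na(cat_idx))[[1L]]
    stop("unknown interaction mode '", trimws(mode[[off]]),
         "' on line ", off + start - 1L)
  }
  self <- id_a == id_b
  if (any(self)) {
    warning(sum(self), " self-interaction row(s) skipped")
    id_a <- id_a[!self]; id_b <- id_b[!self]; cat_idx <- cat_idx[!self]
  }
  if (length(id_a) == 0L) stop("no interactions parsed from ", path)
  ids <- unique(c(rbind(id_a, id_b)))  # first-appearance order, row-wise
  ia <- match(id_a, ids); ib <- match(id_b, ids)
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  key <- paste0(lo, "_", hi)
  ukey <- unique(key)
  edge_of <- match(key, ukey)
  e <- length(ukey)
  edges <- cbind(lo[!duplicated(key)], hi[!duplicated(key)])
  labels <- matrix(0, e, categories$t)
  labels[cbind(edge_of, cat_idx)] <- 1
  protein_graph(ids, edges, labels, categories)
}

#' Write a protein graph as an interaction table
#'
#' Inverse of [read_interactions()]: writes one `(id_a, id_b, mode)` row
#' per edge-category assignment, tab-separated with a header.  Reading
#' the file back yields an isomorphic graph with identical labels.
#'
#' @param graph A [protein_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(graph, path) {
  idx <- which(graph$labels == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  df <- data.frame(
    item_id_a = graph$protein_ids[graph$edges[idx[, 1L], 1L]],
    item_id_b = graph$protein_ids[graph$edges[idx[, 1L], 2L]],
    mode = graph$categories$names[idx[, 2L]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a feature table
#'
#' A feature table maps protein identifiers to fixed-length numeric
#' vectors: first column the identifier, remaining columns the vector,
#' tab- or comma-separated, header optional (detected from whether the
#' second field of the first line parses as a number).
#'
#' @param path Path to the table.
#' @return Numeric matrix with protein identifiers as row names.
#' @export
read_feature_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  f1 <- strsplit(first, sep, fixed = TRUE)[[1L]]
  header <- length(f1) >= 2L &&
    is.na(suppressWarnings(as.numeric(f1[[2L]])))
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) < 2L) stop("feature table needs an id plus >= 1 value")
  ids <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric feature entries in ", path)
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  colnames(mat) <- NULL
  mat
}

#' Write a feature table
#' @param features Numeric matrix with protein identifiers as row names.
#' @param path Output path (tab-separated, no header).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  df <- data.frame(id = rownames(features), features,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Attach vertex features to a graph
#'
#' Aligns a feature table to the graph's protein order.  Every graph
#' protein must appear in the table (missing proteins are an error that
#' names them); table rows for proteins absent from the graph are
#' ignored with a warning.
#'
#' @param graph A [protein_graph()].
#' @param table Path to a feature table (see [read_feature_table()]) or
#'   a numeric matrix with protein identifiers as row names.
#' @return The graph with `features` set (rows follow `protein_ids`).
#' @export
attach_features <- function(graph, table) {
  mat <- if (is.character(table)) read_feature_table(table)
         else as.matrix(table)
  if (is.null(rownames(mat))) stop("feature matrix must have row names")
  missing <- setdiff(graph$protein_ids, rownames(mat))
  if (length(missing))
    stop("feature table is missing protein(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(rownames(mat), graph$protein_ids)
  if (length(extra))
    warning(length(extra), " feature row(s) for proteins not in graph ",
            "ignored")
  set_features(graph, mat[graph$protein_ids, , drop = FALSE])
}

#' Occupation ratios of category counts
#'
#' The occupation ratio of a category is its share of all edge-label
#' assignments: `count_c / sum(counts)`.  The denominator is the total
#' number of label assignments, not the number of edges, because an
#' edge may carry several categories.
#'
#' @param counts Named or unnamed numeric vector of per-category counts.
#' @return Numeric vector of ratios summing to 1.
#' @export
occupation_ratios <- function(counts) {
  counts <- as.numeric(counts0 <- counts)
  if (any(counts < 0) || sum(counts) <= 0)
    stop("counts must be non-negative with a positive total")
  r <- counts / sum(counts)
  names(r) <- names(counts0)
  r
}

#' Per-category sample counts and occupation ratios
#'
#' Tabulates, for each interaction category, the number of edges that
#' carry it and its occupation ratio (share of all label assignments).
#'
#' @param graph A [protein_graph()] with at least one edge.
#' @return A data frame with columns `category`, `count`,
#'   `occupation_ratio`.
#' @examples
#' g <- generate_ppi(easy_setting(n_proteins = 60), seed = 1)
#' category_statistics(g)
#' @export
category_statistics <- function(graph) {
  if (n_edges(graph) < 1L) stop("graph has no edges")
  counts <- colSums(graph$labels)
  data.frame(category = graph$categories$names,
             count = as.numeric(counts),
             occupation_ratio = as.numeric(occupation_ratios(counts)),
             row.names = NULL)
}
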