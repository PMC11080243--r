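#' Construct a protein interaction graph
#'
#' The canonical in-memory container for a multi-label PPI network: an
#' undirected simple graph whose vertices are proteins and whose edges
#' carry a binary label vector over the category space.  Vertex features
#' (one fixed-length numeric vector per protein) are optional and can be
#' attached later with [attach_features()].
#'
#' @param protein_ids Character vector of n unique external identifiers;
#'   vertex i of the graph is `protein_ids[i]`.
#' @param edges Integer matrix with E rows and 2 columns of vertex
#'   indices.  Edges are unordered; rows are canonicalised to
#'   `(min, max)`.  Self-loops and duplicate pairs are errors.
#' @param labels Binary E x t matrix; row e gives the categories of edge
#'   e.  Every edge must carry at least one category.
#' @param categories A [category_space()].
#' @param features Optional n x d numeric matrix of vertex features.
#' @return An object of class `protein_graph`.
#' @seealso [read_interactions()], [category_statistics()]
#' @export
protein_graph <- function(protein_ids, edges, labels,
                          categories = category_space(),
                          features = NULL) {
  protein_ids <- as.character(protein_ids)
  n <- length(protein_ids)
  if (n < 1L) stop("graph needs at least one protein")
  if (anyDuplicated(protein_ids)) stop("duplicate protein identifiers")
  edges <- matrix(as.integer(edges), ncol = 2L)
  labels <- as.matrix(labels)
  storage.mode(labels) <- "double"
  e <- nrow(edges)
  if (e > 0L) {
    if (any(edges < 1L) || any(edges > n)) stop("edge index out of range")
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    if (anyDuplicated(edges)) stop("duplicate edges")
  }
  if (nrow(labels) != e || ncol(labels) != categories$t)
    stop("labels must be an E x t matrix matching edges and categories")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  if (e > 0L && any(rowSums(labels) < 1))
    stop("every edge must carry at least one category")
  dimnames(edges) <- NULL
  colnames(labels) <- categories$names
  g <- structure(list(protein_ids = protein_ids, edges = edges,
                      labels = labels, categories = categories,
                      features = NULL),
                 class = "protein_graph")
  if (!is.null(features)) g <- set_features(g, features)
  g
}

set_features <- function(graph, features) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (nrow(features) != length(graph$protein_ids))
    stop("features must have one row per protein")
  if (!all(is.finite(features))) stop("features must be finite")
  rownames(features) <- graph$protein_ids
  graph$features <- features
  graph
}

#' Number of proteins / edges in a graph
#' @param graph A [protein_graph()].
#' @return Integer count.
#' @export
n_proteins <- function(graph) length(graph$protein_ids)

#' @rdname n_proteins
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' @export
print.protein_graph <- function(x, ...) {
  cat("<protein_graph> ", n_proteins(x), " proteins, ", n_edges(x),
      " edges, ", x$categories$t, " categories",
      if (is.null(x$features)) ", no features"
      else sprintf(", %d-dim features", ncol(x$features)),
      "\n", sep = "")
  invisible(x)
}

# Adjacency as a list of sorted neighbour index vectors.  Restricting to
# a subset of edge rows supports inductive message passing (test edges
# hidden from the encoder).
adjacency_list <- function(graph, edge_idx = NULL) {
  n <- n_proteins(graph)
  ed <- graph$edges
  if (!is.null(edge_idx)) ed <- ed[edge_idx, , drop = FALSE]
  adj <- vector("list", n)
  if (nrow(ed) > 0L) {
    ends <- c(ed[, 1L], ed[, 2L])
    other <- c(ed[, 2L], ed[, 1L])
    sp <- split(other, factor(ends, levels = seq_len(n)))
    adj <- lapply(sp, function(v) sort(unique(as.integer(v))))
  } else {
    adj <- replicate(n, integer(0), simplify = FALSE)
  }
  adj
}

# igraph view of the (optionally edge-restricted) topology.
as_igraph <- function(graph, edge_idx = NULL) {
  ed <- graph$edges
  if (!is.null(edge_idx)) ed <- ed[edge_idx, , drop = FALSE]
  igraph::make_graph(edges = as.integer(t(ed)), n = n_proteins(graph),
                     directed = FALSE)
}

#' Vertex degrees
#' @param graph A [protein_graph()].
#' @return Integer vector of degrees, one per protein.
#' @export
vertex_degrees <- function(graph) {
  tabulate(c(graph$edges[, 1L], graph$edges[, 2L]),
           nbins = n_proteins(graph))
}
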