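#' Extract the k-hop egonet of a vertex
#'
#' The k-hop egonet of vertex `v` is the subgraph induced by all
#' vertices at hop distance at most `k` from `v` (including `v`).
#' Members are ordered deterministically: center first, then ascending
#' vertex index.  Pairwise hop distances are computed *within* the
#' induced subgraph, so a member pair connected only through vertices
#' outside the egonet gets the longer intra-subgraph distance (at most
#' `2k`, through the center).
#'
#' @param graph A [protein_graph()].
#' @param v Center vertex index (1-based).
#' @param k Hop radius, `k >= 0`; `k = 0` gives the singleton egonet.
#' @param edge_idx Optional subset of graph edge rows defining the
#'   topology (used for inductive message passing).
#' @return An object of class `egonet` with fields `center`, `members`
#'   (global vertex indices, center first), `induced_edges` (2-column
#'   matrix of *local* member indices), `dist_to_center`, and
#'   `dist_matrix` (members x members hop distances).
#' @export
extract_egonet <- function(graph, v, k, edge_idx = NULL) {
  n <- n_proteins(graph)
  v <- as.integer(v)
  if (is.na(v) || v < 1L || v > n) stop("invalid vertex index ", v)
  if (k < 0L) stop("k must be >= 0")
  ig <- as_igraph(graph, edge_idx)
  if (k == 0L) {
    return(structure(list(center = v, members = v,
                          induced_edges = matrix(integer(0), 0L, 2L),
                          dist_to_center = 0,
                          dist_matrix = matrix(0, 1L, 1L)),
                     class = "egonet"))
  }
  d <- as.vector(igraph::distances(ig, v = v, mode = "all"))
  reach <- which(is.finite(d) & d <= k)
  members <- c(v, sort(setdiff(reach, v)))
  # igraph ignores the order of vids, so the subgraph lives in
  # sorted-member frame; remap its edges and distances into the
  # center-first member order used everywhere else
  sorted <- sort(members)
  sub <- igraph::induced_subgraph(ig, sorted)
  el <- igraph::as_edgelist(sub, names = FALSE)
  to_local <- match(sorted, members)
  el <- matrix(to_local[el], ncol = 2L)
  pos <- match(members, sorted)
  dm <- igraph::distances(sub, mode = "all")[pos, pos, drop = FALSE]
  dimnames(dm) <- NULL
  structure(list(center = v, members = as.integer(members),
                 induced_edges = matrix(as.integer(el), ncol = 2L),
                 dist_to_center = as.numeric(d[members]),
                 dist_matrix = dm),
            class = "egonet")
}

#' @export
print.egonet <- function(x, ...) {
  cat("<egonet> center", x$center, "with", length(x$members),
      "members,", nrow(x$induced_edges), "induced edges\n")
  invisible(x)
}

#' Intra-subgraph hop-distance matrix of an egonet
#'
#' Accessor for the pairwise shortest-path hop distances between egonet
#' members, computed over the induced edges only.
#'
#' @param egonet An [extract_egonet()] result.
#' @return Symmetric members x members numeric matrix with zero
#'   diagonal.
#' @export
egonet_distance_matrix <- function(egonet) egonet$dist_matrix

#' Batch all egonets of a graph
#'
#' Extracts the k-hop egonet of every vertex and lays them out as one
#' disjoint union so a single kernel-GNN pass can process all subgraphs
#' at once.  The flat layout lists every (egonet, member) pair once;
#' `offsets[v]` is the first flat row of egonet `v`, whose first member
#' is always its center.
#'
#' @param graph A [protein_graph()].
#' @param k Hop radius, `k >= 1`.
#' @param edge_idx Optional topology restriction (see
#'   [extract_egonet()]).
#' @param max_total_members Memory guard: refuse to build the batch if
#'   the disjoint union would exceed this many vertices (large `k` on a
#'   dense graph grows quadratically; use a smaller `k`).
#' @return An object of class `egonet_batch`: `egonets` (list of n
#'   [extract_egonet()] objects), `k`, `member_global` (flat global
#'   vertex index per row), `member_center` (flat center per row),
#'   `member_dist` (flat hop distance to the center), `offsets`,
#'   `union_edges` (2-column matrix over flat indices), and
#'   `center_dist_profile` (n x (2k+1) matrix; row v is the mean
#'   one-hot encoding of the center's distance row, used by the
#'   centroid gate).
#' @export
egonet_batch <- function(graph, k, edge_idx = NULL,
                         max_total_members = 5e6) {
  if (k < 1L) stop("k must be >= 1 for egonet batching")
  n <- n_proteins(graph)
  egos <- lapply(seq_len(n), extract_egonet, graph = graph, k = k,
                 edge_idx = edge_idx)
  sizes <- vapply(egos, function(e) length(e$members), integer(1))
  if (sum(sizes) > max_total_members)
    stop("egonet batch would hold ", sum(sizes),
         " members (> ", max_total_members, "); use a smaller k")
  offsets <- cumsum(c(1L, sizes[-n]))
  union_edges <- do.call(rbind, lapply(seq_len(n), function(v) {
    e <- egos[[v]]$induced_edges
    if (nrow(e)) e + offsets[[v]] - 1L else e
  }))
  nb <- 2L * k + 1L  # distances 0..2k one-hot support
  profile <- t(vapply(egos, function(e) {
    tabulate(pmin(e$dist_to_center, 2 * k) + 1L, nbins = nb) /
      length(e$members)
  }, numeric(nb)))
  structure(list(egonets = egos, k = as.integer(k),
                 member_global = unlist(lapply(egos, `[[`, "members")),
                 member_center = rep.int(seq_len(n), sizes),
                 member_dist = unlist(lapply(egos, `[[`,
                                             "dist_to_center")),
                 offsets = offsets, sizes = sizes,
                 union_edges = union_edges,
                 center_dist_profile = profile),
            class = "egonet_batch")
}

#' @export
print.egonet_batch <- function(x, ...) {
  cat("<egonet_batch> k =", x$k, "|", length(x$egonets), "egonets,",
      length(x$member_global), "union vertices,", nrow(x$union_edges),
      "union edges\n")
  invisible(x)
}
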