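new_edge_split <- function(graph, scheme, test_fraction, seed,
                           test_idx, visited = integer(0),
                           n_restarts = 0L, rule = NA_character_) {
  e <- n_edges(graph)
  test_idx <- sort(unique(as.integer(test_idx)))
  train_idx <- setdiff(seq_len(e), test_idx)
  stopifnot(length(intersect(train_idx, test_idx)) == 0L,
            length(train_idx) + length(test_idx) == e)
  split <- structure(list(scheme = scheme,
                          test_fraction = test_fraction,
                          seed = as.integer(seed),
                          train_idx = as.integer(train_idx),
                          test_idx = test_idx,
                          visited = as.integer(visited),
                          n_restarts = as.integer(n_restarts),
                          rule = rule, n_edges = e),
                     class = "edge_split")
  zero <- colSums(graph$labels[test_idx, , drop = FALSE]) == 0
  if (any(zero))
    warning("no test edges for categor(ies): ",
            paste(graph$categories$names[zero], collapse = ", "),
            call. = FALSE)
  split
}

#' @export
print.edge_split <- function(x, ...) {
  cat("<edge_split> scheme=", x$scheme, " seed=", x$seed, " | ",
      length(x$train_idx), " train / ", length(x$test_idx),
      " test edges (target fraction ", x$test_fraction, ")",
      if (x$n_restarts > 0) paste0(", ", x$n_restarts, " restart(s)"),
      "\n", sep = "")
  invisible(x)
}

#' Random train/test edge partition
#'
#' Samples `round(E * test_fraction)` edges uniformly without
#' replacement as the test set (at least one).
#'
#' @param graph A [protein_graph()].
#' @param test_fraction Target share of edges in the test set, in
#'   (0, 1).
#' @param seed Integer RNG seed; the split is a pure function of
#'   `(graph, scheme, fraction, seed)`.
#' @return An object of class `edge_split` with disjoint, exhaustive
#'   `train_idx` / `test_idx`.
#' @export
random_split <- function(graph, test_fraction = 0.2, seed = 1L) {
  check_fraction(test_fraction)
  e <- n_edges(graph)
  size <- max(1L, round(e * test_fraction))
  if (size >= e) stop("test fraction leaves no training edges")
  test <- with_seed(seed, sample.int(e, size))
  new_edge_split(graph, "random", test_fraction, seed, test)
}

#' Breadth-first (unseen-protein) edge partition
#'
#' Picks a random root protein and traverses proteins breadth-first;
#' each time a protein is taken from the queue, its not-yet-assigned
#' incident edges (default rule `"incident"`) join the test set, until
#' the target edge count is reached.  Test edges therefore cluster
#' around the traversal-discovered proteins, emulating evaluation on
#' unseen proteins.  The final step may overshoot the target; the
#' overshoot is kept and visible in the split sizes.  If a connected
#' component is exhausted before the target, traversal restarts from a
#' new random unvisited protein (`n_restarts` records this).
#'
#' @inheritParams random_split
#' @param rule `"incident"` assigns all unassigned edges of a dequeued
#'   protein; `"visited"` assigns only edges whose two endpoints have
#'   both been dequeued.
#' @return An `edge_split`; `visited` holds the dequeued proteins in
#'   order.
#' @export
bfs_split <- function(graph, test_fraction = 0.2, seed = 1L,
                      rule = c("incident", "visited")) {
  traversal_split(graph, test_fraction, seed, match.arg(rule),
                  scheme = "bfs")
}

#' Depth-first edge partition
#'
#' Identical to [bfs_split()] with a stack replacing the queue.
#'
#' @inheritParams bfs_split
#' @return An `edge_split`.
#' @export
dfs_split <- function(graph, test_fraction = 0.2, seed = 1L,
                      rule = c("incident", "visited")) {
  traversal_split(graph, test_fraction, seed, match.arg(rule),
                  scheme = "dfs")
}

traversal_split <- function(graph, test_fraction, seed, rule, scheme) {
  check_fraction(test_fraction)
  e <- n_edges(graph)
  n <- n_proteins(graph)
  target <- max(1L, round(e * test_fraction))
  if (target >= e) stop("test fraction leaves no training edges")
  adj <- adjacency_list(graph)
  # edge lookup: key (min,max) -> edge row
  ekey <- graph$edges[, 1L] + (graph$edges[, 2L] - 1) * n
  edge_row <- function(i, j)
    match(pmin(i, j) + (pmax(i, j) - 1) * n, ekey)
  with_seed(seed, {
    assigned <- logical(e)
    dequeued <- logical(n)
    discovered <- logical(n)
    visited <- integer(0)
    frontier <- integer(0)        # queue (bfs) or stack (dfs)
    n_restarts <- -1L             # first root is not a restart
    n_test <- 0L
    while (n_test < target) {
      if (length(frontier) == 0L) {
        pool <- which(!discovered)
        if (length(pool) == 0L) break
        root <- pool[[sample.int(length(pool), 1L)]]
        discovered[root] <- TRUE
        frontier <- root
        n_restarts <- n_restarts + 1L
        if (n_restarts > 0L)
          message(scheme, " split: component exhausted, restarting ",
                  "from protein ", graph$protein_ids[root])
      }
      if (scheme == "bfs") {
        v <- frontier[[1L]]; frontier <- frontier[-1L]
      } else {
        v <- frontier[[length(frontier)]]
        frontier <- frontier[-length(frontier)]
      }
      if (dequeued[v]) next
      dequeued[v] <- TRUE
      visited <- c(visited, v)
      nb <- adj[[v]]
      take <- if (rule == "incident") nb else nb[dequeued[nb]]
      if (length(take)) {
        rows <- edge_row(rep.int(v, length(take)), take)
        rows <- rows[!assigned[rows]]
        if (length(rows)) {
          assigned[rows] <- TRUE
          n_test <- n_test + length(rows)
        }
      }
      fresh <- nb[!discovered[nb]]
      discovered[fresh] <- TRUE
      frontier <- c(frontier, fresh)
    }
    if (n_test < target)
      warning(scheme, " traversal exhausted the graph at ", n_test,
              " test edges (target ", target, ")", call. = FALSE)
    new_edge_split(graph, scheme, test_fraction, seed, which(assigned),
                   visited = visited, n_restarts = max(n_restarts, 0L),
                   rule = rule)
  })
}

check_fraction <- function(f) {
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f >= 1)
    stop("test_fraction must lie strictly between 0 and 1")
}

# Evaluate expr under a temporary RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Write / read an edge split
#'
#' Serialises a split as a small TSV with a `#`-comment header carrying
#' scheme, fraction and seed, followed by `(edge_index, part)` rows, so
#' an experiment is exactly re-runnable from its split file.
#'
#' @param split An `edge_split`.
#' @param path Output path.
#' @return `path` invisibly (write); an `edge_split` (read; `graph`
#'   supplies the edge universe and label coverage check).
#' @export
write_split <- function(split, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scheme=%s fraction=%g seed=%d rule=%s",
                     split$scheme, split$test_fraction, split$seed,
                     split$rule), con)
  df <- data.frame(
    edge = c(split$train_idx, split$test_idx),
    part = rep(c("train", "test"),
               c(length(split$train_idx), length(split$test_idx))))
  df <- df[order(df$edge), ]
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @param graph The [protein_graph()] the split refers to.
#' @export
read_split <- function(path, graph) {
  header <- readLines(path, n = 1L)
  meta <- regmatches(header,
                     gregexpr("[a-z_]+=[^ ]+", header))[[1L]]
  kv <- strsplit(meta, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[[`, "", 2L),
                          vapply(kv, `[[`, "", 1L))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#")
  if (max(df$edge) > n_edges(graph)) stop("split does not match graph")
  new_edge_split(graph, vals[["scheme"]],
                 as.numeric(vals[["fraction"]]),
                 as.integer(vals[["seed"]]),
                 df$edge[df$part == "test"],
                 rule = vals[["rule"]])
}
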