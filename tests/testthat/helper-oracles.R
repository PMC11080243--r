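# Independent brute-force oracles used across the suite.  These must
# stay dumb and obvious: no reuse of package internals.

# All-pairs shortest hop distances by Floyd-Warshall.
oracle_floyd_warshall <- function(n, edges) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    d[i, j] <- 1; d[j, i] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Per-source BFS distances restricted to a given edge set.
oracle_bfs_dist <- function(n, edges, src) {
  adj <- replicate(n, integer(0), simplify = FALSE)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  d <- rep(Inf, n); d[src] <- 0
  q <- src
  while (length(q)) {
    v <- q[1]; q <- q[-1]
    for (u in adj[[v]]) if (d[u] > d[v] + 1) {
      d[u] <- d[v] + 1; q <- c(q, u)
    }
  }
  d
}

# Reference multi-label metrics via explicit per-category loops.
oracle_metrics <- function(pred, truth, averaging) {
  t <- ncol(truth)
  tp <- fp <- fn <- numeric(t)
  for (c in seq_len(t)) for (e in seq_len(nrow(truth))) {
    if (pred[e, c] == 1 && truth[e, c] == 1) tp[c] <- tp[c] + 1
    if (pred[e, c] == 1 && truth[e, c] == 0) fp[c] <- fp[c] + 1
    if (pred[e, c] == 0 && truth[e, c] == 1) fn[c] <- fn[c] + 1
  }
  div <- function(a, b) if (b == 0) 0 else a / b
  p <- mapply(div, tp, tp + fp)
  r <- mapply(div, tp, tp + fn)
  f <- mapply(function(pp, rr) div(2 * pp * rr, pp + rr), p, r)
  if (averaging == "micro") {
    mp <- div(sum(tp), sum(tp) + sum(fp))
    mr <- div(sum(tp), sum(tp) + sum(fn))
    c(precision = mp, recall = mr, f1 = div(2 * mp * mr, mp + mr))
  } else if (averaging == "macro") {
    c(precision = mean(p), recall = mean(r), f1 = mean(f))
  } else {
    w <- (tp + fn) / sum(tp + fn)
    c(precision = sum(w * p), recall = sum(w * r), f1 = sum(w * f))
  }
}

# Unbatched reference of the local subgraph encoder: loops over
# egonets, runs the kernel GIN on each one densely, gates by one-hot
# distances and applies the model's eval-mode batch-norm affine.
oracle_local_encoder <- function(model, graph) {
  p <- model$params
  cfg <- model$config
  k <- cfg$k
  relu0 <- function(x) pmax(x, 0)
  sig <- function(x) 1 / (1 + exp(-x))
  gate <- function(inp) {
    sig(relu0(sweep(inp %*% p$aW1, 2, p$ab1, "+")) %*% p$aW2 +
          matrix(p$ab2, nrow(inp), length(p$ab2), byrow = TRUE))
  }
  h2 <- cfg$hidden_dim / 2
  n <- n_proteins(graph)
  pre <- matrix(0, n, h2)
  for (v in seq_len(n)) {
    ego <- extract_egonet(graph, v, k)
    Xe <- graph$features[ego$members, , drop = FALSE]
    A <- matrix(0, length(ego$members), length(ego$members))
    for (r in seq_len(nrow(ego$induced_edges))) {
      i <- ego$induced_edges[r, 1]; j <- ego$induced_edges[r, 2]
      A[i, j] <- 1; A[j, i] <- 1
    }
    S <- (1 + cfg$gin_epsilon) * Xe + A %*% Xe
    L2 <- relu0(sweep(relu0(sweep(S %*% p$lW1, 2, p$lb1, "+")) %*%
                        p$lW2, 2, p$lb2, "+"))
    nb <- 2 * k + 1
    onehot <- matrix(0, length(ego$members), nb)
    onehot[cbind(seq_along(ego$members),
                 pmin(ego$dist_to_center, 2 * k) + 1)] <- 1
    gs <- gate(onehot)
    h_sub <- colSums(gs * L2)
    profile <- matrix(colMeans(onehot), 1, nb)
    gc_ <- gate(profile)
    h_cent <- as.numeric(gc_) * L2[1, ]
    pre[v, ] <- h_sub + h_cent
  }
  # eval-mode batch-norm affine with the model's running statistics
  xhat <- sweep(sweep(pre, 2, model$state$l_mean), 2,
                sqrt(model$state$l_var + 1e-5), "/")
  sweep(sweep(xhat, 2, p$lGamma, "*"), 2, p$lBeta, "+")
}

# Small graph builders ------------------------------------------------

# Path graph a-b-c-...; labels: one deterministic category per edge.
make_path_graph <- function(n, t = 7) {
  edges <- cbind(seq_len(n - 1), seq_len(n - 1) + 1)
  labels <- matrix(0, n - 1, t)
  labels[cbind(seq_len(n - 1), rep_len(seq_len(t), n - 1))] <- 1
  protein_graph(paste0("p", seq_len(n)), edges, labels)
}

# Star K_{1,m} with the center as vertex 1.
make_star_graph <- function(m, t = 7) {
  edges <- cbind(rep(1L, m), seq_len(m) + 1L)
  labels <- matrix(0, m, t)
  labels[, 1] <- 1
  protein_graph(paste0("p", seq_len(m + 1)), edges, labels)
}

# Erdos-Renyi graph as a protein_graph (single random label/edge);
# resamples until it has >= 1 edge.  connected = TRUE retries until the
# graph is connected (checked by BFS reach).
make_random_graph <- function(n, p, t = 7, connected = FALSE) {
  repeat {
    idx <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(idx)) < p
    if (!any(keep)) next
    edges <- idx[keep, , drop = FALSE]
    if (connected &&
        any(is.infinite(oracle_bfs_dist(n, edges, 1)))) next
    labels <- matrix(0, nrow(edges), t)
    labels[cbind(seq_len(nrow(edges)),
                 sample.int(t, nrow(edges), replace = TRUE))] <- 1
    return(protein_graph(paste0("p", seq_len(n)), edges, labels))
  }
}

# Tiny featured graph + small model, shared by model-level tests.
make_model_fixture <- function(n = 16, seed = 5, hidden = 8, k = 1,
                               paths = "both", dropout = 0) {
  set.seed(seed)
  g <- make_random_graph(n, 0.25)
  g <- attach_features(g, {
    X <- matrix(stats::rnorm(n * 4), n, 4)
    rownames(X) <- g$protein_ids
    X
  })
  cfg <- model_config(input_dim = 4, hidden_dim = hidden, k = k,
                      dropout_local = dropout, dropout_global = dropout,
                      seed = seed, paths = paths)
  m <- ppi_model(cfg)
  # tie-break ReLU kinks left exactly at zero by the zero bias init
  m$params <- lapply(m$params, function(x)
    x + stats::rnorm(length(x), sd = 0.03))
  list(graph = g, model = m, config = cfg)
}
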