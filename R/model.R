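#' Model configuration
#'
#' Hyperparameters of the edge classifier.  The network has two
#' branches of width `hidden_dim / 2` each: a global GIN encoder over
#' the whole PPI graph (one GIN layer, two fully connected ReLU layers,
#' batch normalisation, dropout `dropout_global`) and a local
#' subgraph-as-kernel encoder that runs a shared GIN over every
#' vertex's k-hop egonet and combines a distance-gated sum over members
#' with a gated center ("centroid") embedding (dropout
#' `dropout_local`).  Fused vertex features are multiplied elementwise
#' across each edge's endpoints and mapped by one fully connected layer
#' to per-category probabilities.
#'
#' @param input_dim Vertex feature length d.
#' @param hidden_dim Total fused width h (split evenly across
#'   branches); must be even.
#' @param k Egonet hop radius (default 1; larger k grows the egonet
#'   batch quickly).
#' @param dropout_local,dropout_global Dropout rates in `[0, 1)` for
#'   the two branches.
#' @param n_categories Number of interaction categories t.
#' @param seed Seed for parameter initialisation.
#' @param gin_epsilon GIN self-weight epsilon (both encoders).
#' @param epsilon_learnable Should epsilon be trained?
#' @param paths Which branches feed the classifier head: `"both"`
#'   (default), `"global"` or `"local"` (ablation switches).
#' @return A list of class `model_config`.
#' @export
model_config <- function(input_dim, hidden_dim = 512L, k = 1L,
                         dropout_local = 0.2, dropout_global = 0.5,
                         n_categories = 7L, seed = 1L,
                         gin_epsilon = 0, epsilon_learnable = FALSE,
                         paths = c("both", "global", "local")) {
  paths <- match.arg(paths)
  stopifnot(input_dim >= 1L, hidden_dim >= 2L, hidden_dim %% 2L == 0L,
            k >= 0L, n_categories >= 1L,
            dropout_local >= 0, dropout_local < 1,
            dropout_global >= 0, dropout_global < 1)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dim = as.integer(hidden_dim),
                 k = as.integer(k),
                 dropout_local = dropout_local,
                 dropout_global = dropout_global,
                 n_categories = as.integer(n_categories),
                 seed = as.integer(seed),
                 gin_epsilon = gin_epsilon,
                 epsilon_learnable = isTRUE(epsilon_learnable),
                 paths = paths),
            class = "model_config")
}

glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))),
         nin, nout)
}

#' Initialise an edge classifier
#'
#' Creates the parameter tensors (seeded Glorot-normal) and batch-norm
#' running statistics for a [model_config()].
#'
#' @param config A [model_config()].
#' @return An object of class `ppi_model` with fields `config`,
#'   `params` (named list of weight matrices/vectors) and `state`
#'   (batch-norm running statistics per branch).
#' @export
ppi_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  d <- config$input_dim
  h2 <- config$hidden_dim %/% 2L
  t <- config$n_categories
  nb <- 2L * config$k + 1L
  head_in <- if (config$paths == "both") 2L * h2 else h2
  params <- with_seed(config$seed, list(
    gW1 = glorot(d, h2),  gb1 = numeric(h2),
    gW2 = glorot(h2, h2), gb2 = numeric(h2),
    gW3 = glorot(h2, h2), gb3 = numeric(h2),
    gW4 = glorot(h2, h2), gb4 = numeric(h2),
    gGamma = rep(1, h2),  gBeta = numeric(h2),
    lW1 = glorot(d, h2),  lb1 = numeric(h2),
    lW2 = glorot(h2, h2), lb2 = numeric(h2),
    aW1 = glorot(max(nb, 1L), h2), ab1 = numeric(h2),
    aW2 = glorot(h2, h2), ab2 = numeric(h2),
    lGamma = rep(1, h2),  lBeta = numeric(h2),
    hW = glorot(head_in, t), hb = numeric(t)))
  if (config$epsilon_learnable) {
    params$eps_g <- config$gin_epsilon
    params$eps_l <- config$gin_epsilon
  }
  structure(list(config = config, params = params,
                 state = list(g_mean = numeric(h2), g_var = rep(1, h2),
                              l_mean = numeric(h2), l_var = rep(1, h2))),
            class = "ppi_model")
}

#' @export
print.ppi_model <- function(x, ...) {
  cfg <- x$config
  cat("<ppi_model> d=", cfg$input_dim, " h=", cfg$hidden_dim,
      " k=", cfg$k, " t=", cfg$n_categories, " paths=", cfg$paths,
      " | ", sum(vapply(x$params, length, integer(1))),
      " parameters\n", sep = "")
  invisible(x)
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))
addb <- function(x, b) sweep(x, 2L, b, "+")
densify <- function(x) as.matrix(x)

# Message-passing context: sparse operators shared by every forward
# pass on one (graph topology, k) pair.
mp_context <- function(graph, config, edge_idx = NULL, batch = NULL) {
  n <- n_proteins(graph)
  ed <- graph$edges
  if (!is.null(edge_idx)) ed <- ed[edge_idx, , drop = FALSE]
  Ag <- Matrix::sparseMatrix(i = c(ed[, 1L], ed[, 2L]),
                             j = c(ed[, 2L], ed[, 1L]),
                             x = 1, dims = c(n, n))
  ctx <- list(n = n, Ag = Ag)
  if (config$paths != "global" && config$k >= 1L) {
    if (is.null(batch)) batch <- egonet_batch(graph, config$k, edge_idx)
    f <- length(batch$member_global)
    ue <- batch$union_edges
    ctx$batch <- batch
    ctx$Au <- Matrix::sparseMatrix(i = c(ue[, 1L], ue[, 2L]),
                                   j = c(ue[, 2L], ue[, 1L]),
                                   x = 1, dims = c(f, f))
    ctx$Gsel <- batch$member_global       # gather rows of X
    ctx$Pcen <- Matrix::sparseMatrix(i = batch$member_center,
                                     j = seq_len(f), x = 1,
                                     dims = c(n, f))
    nb <- 2L * config$k + 1L
    ctx$D1 <- Matrix::sparseMatrix(
      i = seq_len(f), j = pmin(batch$member_dist, 2 * config$k) + 1L,
      x = 1, dims = c(f, nb))
    ctx$D1 <- densify(ctx$D1)
    ctx$Cenc <- batch$center_dist_profile
    ctx$offsets <- batch$offsets
  }
  ctx
}

dropout_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix(stats::rbinom(nr * nc, 1L, 1 - rate) / (1 - rate), nr, nc)
}

bn_forward <- function(x, gamma, beta, run_mean, run_var, train) {
  if (train) {
    mu <- colMeans(x)
    va <- colMeans(sweep(x, 2L, mu)^2)   # biased batch variance
    xc <- sweep(x, 2L, mu)
    sd_ <- sqrt(va + BN_EPS)
    xhat <- sweep(xc, 2L, sd_, "/")
    list(y = addb(sweep(xhat, 2L, gamma, "*"), beta),
         xhat = xhat, sd = sd_, mu = mu, va = va)
  } else {
    sd_ <- sqrt(run_var + BN_EPS)
    xhat <- sweep(sweep(x, 2L, run_mean), 2L, sd_, "/")
    list(y = addb(sweep(xhat, 2L, gamma, "*"), beta),
         xhat = xhat, sd = sd_)
  }
}

bn_backward <- function(dy, cache, gamma, train) {
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  if (train) {
    n <- nrow(dy)
    t1 <- sweep(dy, 2L, colSums(dy) / n)
    t2 <- sweep(cache$xhat, 2L, colSums(dy * cache$xhat) / n, "*")
    dx <- sweep(t1 - t2, 2L, gamma / cache$sd, "*")
  } else {
    dx <- sweep(dy, 2L, gamma / cache$sd, "*")
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Full vertex-encoder forward pass.  mode "train" draws dropout masks
# from the current RNG stream and uses batch BN statistics (updating
# the running ones in the returned state); "eval" is deterministic.
forward_vertex <- function(model, X, ctx, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  train <- mode == "train"
  p <- model$params
  cfg <- model$config
  st <- model$state
  eps_g <- if (cfg$epsilon_learnable) p$eps_g else cfg$gin_epsilon
  eps_l <- if (cfg$epsilon_learnable) p$eps_l else cfg$gin_epsilon
  cache <- list(mode = mode, X = X)
  glob <- loc <- NULL

  if (cfg$paths != "local") {
    Sg <- (1 + eps_g) * X + densify(ctx$Ag %*% X)
    Z1 <- addb(Sg %*% p$gW1, p$gb1); A1 <- relu(Z1)
    Z2 <- addb(A1 %*% p$gW2, p$gb2); A2 <- relu(Z2)
    Z3 <- addb(A2 %*% p$gW3, p$gb3); A3 <- relu(Z3)
    M3 <- if (train) dropout_mask(nrow(A3), ncol(A3),
                                  cfg$dropout_global) else NULL
    D3 <- if (is.null(M3)) A3 else A3 * M3
    Z4 <- addb(D3 %*% p$gW4, p$gb4); A4 <- relu(Z4)
    M4 <- if (train) dropout_mask(nrow(A4), ncol(A4),
                                  cfg$dropout_global) else NULL
    D4 <- if (is.null(M4)) A4 else A4 * M4
    bn <- bn_forward(D4, p$gGamma, p$gBeta, st$g_mean, st$g_var, train)
    glob <- bn$y
    if (train) {
      st$g_mean <- (1 - BN_MOMENTUM) * st$g_mean + BN_MOMENTUM * bn$mu
      st$g_var <- (1 - BN_MOMENTUM) * st$g_var + BN_MOMENTUM * bn$va
    }
    cache$g <- list(Sg = Sg, Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2,
                    Z3 = Z3, A3 = A3, M3 = M3, D3 = D3, Z4 = Z4,
                    A4 = A4, M4 = M4, D4 = D4, bn = bn)
  }

  if (cfg$paths != "global") {
    if (cfg$k >= 1L) {
      Xu <- X[ctx$Gsel, , drop = FALSE]
      Su <- (1 + eps_l) * Xu + densify(ctx$Au %*% Xu)
    } else {
      Xu <- X
      Su <- (1 + eps_l) * X
    }
    L1z <- addb(Su %*% p$lW1, p$lb1); L1 <- relu(L1z)
    L2z <- addb(L1 %*% p$lW2, p$lb2); L2 <- relu(L2z)
    gate_fwd <- function(inp) {
      Gz1 <- addb(inp %*% p$aW1, p$ab1); Ga1 <- relu(Gz1)
      Gm <- if (train) dropout_mask(nrow(Ga1), ncol(Ga1),
                                    cfg$dropout_local) else NULL
      Gd1 <- if (is.null(Gm)) Ga1 else Ga1 * Gm
      Gz2 <- addb(Gd1 %*% p$aW2, p$ab2)
      list(inp = inp, Gz1 = Gz1, Ga1 = Ga1, Gm = Gm, Gd1 = Gd1,
           Gz2 = Gz2, g = sigmoid(Gz2))
    }
    if (cfg$k >= 1L) {
      gs <- gate_fwd(ctx$D1)
      gc <- gate_fwd(ctx$Cenc)
      gated <- gs$g * L2
      h_sub <- densify(ctx$Pcen %*% gated)
      h_center <- L2[ctx$offsets, , drop = FALSE]
      h_cent <- gc$g * h_center
    } else {
      # singleton egonets: both branches gate the vertex's own
      # embedding with the distance-0 encoding
      onehot0 <- matrix(0, nrow(X), max(1L, 2L * cfg$k + 1L))
      onehot0[, 1L] <- 1
      gs <- gate_fwd(onehot0)
      gc <- gate_fwd(onehot0)
      gated <- gs$g * L2
      h_sub <- gated
      h_center <- L2
      h_cent <- gc$g * h_center
    }
    pre <- h_sub + h_cent
    bnl <- bn_forward(pre, p$lGamma, p$lBeta, st$l_mean, st$l_var,
                      train)
    loc <- bnl$y
    if (train) {
      st$l_mean <- (1 - BN_MOMENTUM) * st$l_mean + BN_MOMENTUM * bnl$mu
      st$l_var <- (1 - BN_MOMENTUM) * st$l_var + BN_MOMENTUM * bnl$va
    }
    cache$l <- list(Xu = Xu, Su = Su, L1z = L1z, L1 = L1, L2z = L2z,
                    L2 = L2, gs = gs, gc = gc, gated = gated,
                    h_sub = h_sub, h_center = h_center,
                    h_cent = h_cent, pre = pre, bn = bnl)
  }

  H <- switch(cfg$paths,
              both = cbind(glob, loc),
              global = glob,
              local = loc)
  list(H = H, global = glob, local = loc, cache = cache, state = st)
}

# Backward pass: dH (n x head_in) -> parameter gradients (+ nothing
# for X, which is fixed input).  Returns a named list aligned with
# model$params.
backward_vertex <- function(model, ctx, cache, dH) {
  p <- model$params
  cfg <- model$config
  h2 <- cfg$hidden_dim %/% 2L
  train <- cache$mode == "train"
  X <- cache$X
  grads <- lapply(p, function(x) if (is.matrix(x)) 0 * x else 0 * x)
  eps_l <- if (cfg$epsilon_learnable) p$eps_l else cfg$gin_epsilon

  if (cfg$paths == "both") {
    dglob <- dH[, seq_len(h2), drop = FALSE]
    dloc <- dH[, h2 + seq_len(h2), drop = FALSE]
  } else if (cfg$paths == "global") {
    dglob <- dH; dloc <- NULL
  } else {
    dglob <- NULL; dloc <- dH
  }

  if (!is.null(dglob)) {
    g <- cache$g
    bb <- bn_backward(dglob, g$bn, p$gGamma, train)
    grads$gGamma <- bb$dgamma; grads$gBeta <- bb$dbeta
    dD4 <- bb$dx
    dA4 <- if (is.null(g$M4)) dD4 else dD4 * g$M4
    dZ4 <- dA4 * (g$Z4 > 0)
    grads$gW4 <- crossprod(g$D3, dZ4); grads$gb4 <- colSums(dZ4)
    dD3 <- dZ4 %*% t(p$gW4)
    dA3 <- if (is.null(g$M3)) dD3 else dD3 * g$M3
    dZ3 <- dA3 * (g$Z3 > 0)
    grads$gW3 <- crossprod(g$A2, dZ3); grads$gb3 <- colSums(dZ3)
    dA2 <- dZ3 %*% t(p$gW3)
    dZ2 <- dA2 * (g$Z2 > 0)
    grads$gW2 <- crossprod(g$A1, dZ2); grads$gb2 <- colSums(dZ2)
    dA1 <- dZ2 %*% t(p$gW2)
    dZ1 <- dA1 * (g$Z1 > 0)
    grads$gW1 <- crossprod(g$Sg, dZ1); grads$gb1 <- colSums(dZ1)
    if (cfg$epsilon_learnable) {
      dSg <- dZ1 %*% t(p$gW1)
      grads$eps_g <- sum(dSg * X)
    }
  }

  if (!is.null(dloc)) {
    l <- cache$l
    bb <- bn_backward(dloc, l$bn, p$lGamma, train)
    grads$lGamma <- bb$dgamma; grads$lBeta <- bb$dbeta
    dpre <- bb$dx
    # centroid branch
    dgc_g <- dpre * l$h_center
    dh_center <- dpre * l$gc$g
    # subgraph branch
    if (cfg$k >= 1L) {
      dgated <- densify(Matrix::crossprod(ctx$Pcen, dpre))
    } else {
      dgated <- dpre
    }
    dgs_g <- dgated * l$L2
    dL2 <- dgated * l$gs$g
    if (cfg$k >= 1L) {
      dL2[ctx$offsets, ] <- dL2[ctx$offsets, , drop = FALSE] +
        dh_center
    } else {
      dL2 <- dL2 + dh_center
    }
    gate_bwd <- function(gcache, dg) {
      dGz2 <- dg * gcache$g * (1 - gcache$g)
      aW2g <- crossprod(gcache$Gd1, dGz2)
      ab2g <- colSums(dGz2)
      dGd1 <- dGz2 %*% t(p$aW2)
      dGa1 <- if (is.null(gcache$Gm)) dGd1 else dGd1 * gcache$Gm
      dGz1 <- dGa1 * (gcache$Gz1 > 0)
      list(aW1 = crossprod(gcache$inp, dGz1), ab1 = colSums(dGz1),
           aW2 = aW2g, ab2 = ab2g)
    }
    gb_s <- gate_bwd(l$gs, dgs_g)
    gb_c <- gate_bwd(l$gc, dgc_g)
    grads$aW1 <- gb_s$aW1 + gb_c$aW1
    grads$ab1 <- gb_s$ab1 + gb_c$ab1
    grads$aW2 <- gb_s$aW2 + gb_c$aW2
    grads$ab2 <- gb_s$ab2 + gb_c$ab2
    dL2z <- dL2 * (l$L2z > 0)
    grads$lW2 <- crossprod(l$L1, dL2z); grads$lb2 <- colSums(dL2z)
    dL1 <- dL2z %*% t(p$lW2)
    dL1z <- dL1 * (l$L1z > 0)
    grads$lW1 <- crossprod(l$Su, dL1z); grads$lb1 <- colSums(dL1z)
    if (cfg$epsilon_learnable) {
      dSu <- dL1z %*% t(p$lW1)
      grads$eps_l <- sum(dSu * l$Xu)
    }
  }
  grads
}

#' Single GIN vertex update
#'
#' The standard Graph Isomorphism Network update
#' `h_v = MLP((1 + eps) x_v + sum_{u in N(v)} x_u)` with a two-layer
#' ReLU MLP, evaluated for every vertex at once.
#'
#' @param X n x d feature matrix.
#' @param graph A [protein_graph()] supplying the neighbourhoods.
#' @param params List with `W1` (d x h), `b1`, `W2` (h x h'), `b2` and
#'   optional `eps` (default 0).
#' @return n x h' matrix of updated vertex features.
#' @export
gin_update <- function(X, graph, params) {
  X <- as.matrix(X)
  if (nrow(X) != n_proteins(graph)) stop("X must have one row per protein")
  if (!all(is.finite(X))) stop("X must be finite")
  eps <- params$eps %||% 0
  ed <- graph$edges
  Ag <- Matrix::sparseMatrix(i = c(ed[, 1L], ed[, 2L]),
                             j = c(ed[, 2L], ed[, 1L]),
                             x = 1, dims = rep(n_proteins(graph), 2L))
  S <- (1 + eps) * X + densify(Ag %*% X)
  relu(addb(relu(addb(S %*% params$W1, params$b1)) %*% params$W2,
            params$b2))
}

#' Fused vertex embeddings
#'
#' Runs the configured encoder branches over the graph and returns the
#' fused per-vertex representation (global block first, then local).
#' In `"eval"` mode the result is deterministic (no dropout, running
#' batch-norm statistics).
#'
#' @param model A [ppi_model()].
#' @param graph A [protein_graph()] with features attached.
#' @param mode `"eval"` (default) or `"train"`.
#' @param edge_idx Optional edge subset used for message passing
#'   (inductive protocols).
#' @param batch Optional precomputed [egonet_batch()].
#' @return List with `H` (n x width fused matrix), `global`, `local`.
#' @export
vertex_embeddings <- function(model, graph, mode = c("eval", "train"),
                              edge_idx = NULL, batch = NULL) {
  mode <- match.arg(mode)
  if (is.null(graph$features)) stop("graph has no features attached")
  ctx <- mp_context(graph, model$config, edge_idx, batch)
  fw <- forward_vertex(model, graph$features, ctx, mode)
  fw[c("H", "global", "local")]
}

#' Fuse global and local branch features
#'
#' Column-concatenates the two branch outputs into the final vertex
#' representation.
#'
#' @param global n x h/2 global-branch matrix.
#' @param local n x h/2 local-branch matrix.
#' @return n x h fused matrix.
#' @export
fuse <- function(global, local) {
  if (nrow(global) != nrow(local)) stop("row count mismatch")
  cbind(global, local)
}

#' Predict per-category edge probabilities
#'
#' For each edge (i, j), multiplies the two endpoint embeddings
#' elementwise, applies the fully connected head and a sigmoid.  The
#' elementwise product is symmetric, so probabilities do not depend on
#' endpoint order.
#'
#' @param model A [ppi_model()] (supplies the head parameters).
#' @param H n x width fused embedding matrix from
#'   [vertex_embeddings()].
#' @param edges Integer matrix (E x 2) of vertex index pairs.
#' @return E x t matrix of probabilities strictly inside (0, 1).
#' @export
predict_edges <- function(model, H, edges) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (any(edges < 1L) || any(edges > nrow(H)))
    stop("invalid edge vertex index")
  Q <- H[edges[, 1L], , drop = FALSE] * H[edges[, 2L], , drop = FALSE]
  P <- sigmoid(addb(Q %*% model$params$hW, model$params$hb))
  dimnames(P) <- NULL
  pmin(pmax(P, PROB_EPS), 1 - PROB_EPS)
}
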