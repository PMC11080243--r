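#' Training configuration
#'
#' Defaults follow the reference training recipe for this model family:
#' Adam, up to 400 epochs, batches of 1024 edges, initial learning rate
#' 0.01, early stopping when the training loss has not improved for
#' `patience = 20` epochs, and the asymmetric loss with
#' `gamma_pos = 1`, `gamma_neg = 0`, margin `0.05`.  The learning rate
#' is halved whenever the loss fails to improve for `patience / 2`
#' consecutive epochs.
#'
#' @param epochs Maximum number of epochs.
#' @param batch_size Edges per optimisation step.
#' @param lr Initial learning rate.
#' @param patience Epochs without loss improvement before stopping.
#' @param lr_decay Multiplicative decay factor applied on plateau.
#' @param seed RNG seed for batch shuffling and dropout.
#' @param loss `"asl"`, `"bce"` or `"focal"`.
#' @param loss_params [asl_params()] used when `loss = "asl"`.
#' @param gamma Focusing exponent used when `loss = "focal"`.
#' @param transductive If `TRUE` (default) message passing runs on the
#'   full graph and only the loss is restricted to training edges; if
#'   `FALSE`, test edges are also hidden from the encoders.
#' @param eval_each_epoch If `TRUE`, record test micro-F1 per epoch in
#'   the history (slower).
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 400L, batch_size = 1024L, lr = 0.01,
                         patience = 20L, lr_decay = 0.5, seed = 1L,
                         loss = c("asl", "bce", "focal"),
                         loss_params = asl_params(), gamma = 2,
                         transductive = TRUE,
                         eval_each_epoch = FALSE) {
  loss <- match.arg(loss)
  stopifnot(epochs >= 1L, batch_size >= 1L, lr >= 0, patience >= 1L,
            lr_decay > 0, lr_decay <= 1)  # lr = 0 freezes the model
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 patience = as.integer(patience), lr_decay = lr_decay,
                 seed = as.integer(seed), loss = loss,
                 loss_params = loss_params, gamma = gamma,
                 transductive = isTRUE(transductive),
                 eval_each_epoch = isTRUE(eval_each_epoch)),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) 0 * x),
       v = lapply(params, function(x) 0 * x),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(params, grads, opt, lr) {
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$beta1^opt$t
  c2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + opt$eps)
  }
  list(params = params, opt = opt)
}

#' Train the edge classifier
#'
#' Seeded mini-batch training with Adam on the training edges of a
#' split.  Vertex embeddings are recomputed on the (transductively)
#' visible graph at every step; the loss only ever sees training
#' edges.  Early stopping monitors the epoch-mean training loss; the
#' parameters from the best epoch are retained.
#'
#' @param graph A [protein_graph()] with features.
#' @param split An `edge_split` from [random_split()], [bfs_split()] or
#'   [dfs_split()].
#' @param mconfig A [model_config()]; its `input_dim` and
#'   `n_categories` must match the graph.
#' @param tconfig A [train_config()].
#' @return An object of class `ppi_fit`: the best `model`, the final
#'   `model_last`, a `history` data frame (epoch, loss, lr, test_f1),
#'   `stop_reason` (`"early_stop"` or `"max_epochs"`) and
#'   `best_epoch`.
#' @export
train_ppi <- function(graph, split, mconfig, tconfig = train_config()) {
  if (is.null(graph$features)) stop("graph has no features attached")
  stopifnot(inherits(split, "edge_split"))
  if (mconfig$input_dim != ncol(graph$features))
    stop("model input_dim does not match feature dimension")
  if (mconfig$n_categories != graph$categories$t)
    stop("model n_categories does not match the category space")
  edge_idx <- if (tconfig$transductive) NULL else split$train_idx
  model <- ppi_model(mconfig)
  ctx <- mp_context(graph, mconfig, edge_idx)
  lossfn <- resolve_loss(tconfig$loss, tconfig$loss_params,
                         tconfig$gamma)
  opt <- adam_init(model$params)
  train_edges <- split$train_idx
  if (length(train_edges) < 1L) stop("empty training split")
  Y <- graph$labels
  X <- graph$features
  lr <- tconfig$lr
  best_loss <- Inf; best_epoch <- 0L; best <- model
  since_improve <- 0L; since_decay <- 0L
  hist <- vector("list", tconfig$epochs)
  stop_reason <- "max_epochs"
  decay_every <- max(1L, tconfig$patience %/% 2L)
  with_seed(tconfig$seed, {
    for (epoch in seq_len(tconfig$epochs)) {
      perm <- sample(train_edges)
      nb <- ceiling(length(perm) / tconfig$batch_size)
      ep_loss <- 0
      for (b in seq_len(nb)) {
        take <- perm[seq.int((b - 1L) * tconfig$batch_size + 1L,
                             min(b * tconfig$batch_size,
                                 length(perm)))]
        fw <- forward_vertex(model, X, ctx, "train")
        model$state <- fw$state
        ed <- graph$edges[take, , drop = FALSE]
        Hi <- fw$H[ed[, 1L], , drop = FALSE]
        Hj <- fw$H[ed[, 2L], , drop = FALSE]
        Q <- Hi * Hj
        Z <- addb(Q %*% model$params$hW, model$params$hb)
        P <- pmin(pmax(sigmoid(Z), PROB_EPS), 1 - PROB_EPS)
        yb <- Y[take, , drop = FALSE]
        lval <- lossfn$value(P, yb)
        if (!is.finite(lval))
          stop("non-finite loss at epoch ", epoch, " batch ", b,
               " (lr = ", lr, "); training aborted")
        ep_loss <- ep_loss + lval * length(take)
        dZ <- lossfn$grad(P, yb) * P * (1 - P)
        dH <- scatter_edge_grad(dZ, model, Q, Hi, Hj, ed, nrow(fw$H))
        grads <- backward_vertex(model, ctx, fw$cache, dH)
        gq <- attr(dH, "head")
        grads$hW <- gq$hW; grads$hb <- gq$hb
        upd <- adam_step(model$params, grads, opt, lr)
        model$params <- upd$params
        opt <- upd$opt
      }
      ep_loss <- ep_loss / length(perm)
      test_f1 <- NA_real_
      if (tconfig$eval_each_epoch)
        test_f1 <- evaluate_ppi(model, graph, split,
                                edge_idx = edge_idx)$primary_f1
      hist[[epoch]] <- data.frame(epoch = epoch, loss = ep_loss,
                                  lr = lr, test_f1 = test_f1)
      if (ep_loss < best_loss - 1e-12) {
        best_loss <- ep_loss; best_epoch <- epoch; best <- model
        since_improve <- 0L; since_decay <- 0L
      } else {
        since_improve <- since_improve + 1L
        since_decay <- since_decay + 1L
        if (since_decay >= decay_every) {
          lr <- lr * tconfig$lr_decay
          since_decay <- 0L
        }
        if (since_improve >= tconfig$patience) {
          stop_reason <- "early_stop"
          break
        }
      }
    }
  })
  structure(list(model = best, model_last = model,
                 history = do.call(rbind, hist[!vapply(hist, is.null,
                                                       logical(1))]),
                 stop_reason = stop_reason, best_epoch = best_epoch,
                 best_loss = best_loss,
                 mconfig = mconfig, tconfig = tconfig,
                 split_meta = split[c("scheme", "test_fraction",
                                      "seed")]),
            class = "ppi_fit")
}

# Head gradients + scatter of edge gradients back onto vertex rows.
# Returns dH and stashes head parameter gradients as an attribute.
scatter_edge_grad <- function(dZ, model, Q, Hi, Hj, ed, n) {
  dQ <- dZ %*% t(model$params$hW)
  dHi <- dQ * Hj
  dHj <- dQ * Hi
  grp <- c(ed[, 1L], ed[, 2L])
  dall <- rbind(dHi, dHj)
  agg <- rowsum(dall, group = grp)
  dH <- matrix(0, n, ncol(dall))
  dH[as.integer(rownames(agg)), ] <- agg
  attr(dH, "head") <- list(hW = crossprod(Q, dZ), hb = colSums(dZ))
  dH
}

#' @export
print.ppi_fit <- function(x, ...) {
  cat("<ppi_fit> ", nrow(x$history), " epochs (best ", x$best_epoch,
      ", loss ", signif(x$best_loss, 5), "), stop: ", x$stop_reason,
      "\n", sep = "")
  invisible(x)
}

#' Evaluate a trained model on the test edges of a split
#'
#' Computes deterministic (eval-mode) embeddings, predicts the test
#' edges at the 0.5 threshold and returns the full
#' [metrics_report()].
#'
#' @param fit A `ppi_fit` or a bare `ppi_model`.
#' @param graph The featured [protein_graph()].
#' @param split The `edge_split` whose `test_idx` is evaluated.
#' @param threshold Decision threshold on the sigmoid outputs.
#' @param edge_idx Optional message-passing restriction (must match
#'   training for inductive runs).
#' @return A [metrics_report()].
#' @export
evaluate_ppi <- function(fit, graph, split, threshold = 0.5,
                         edge_idx = NULL) {
  model <- if (inherits(fit, "ppi_fit")) fit$model else fit
  if (is.null(graph$features)) stop("graph has no features attached")
  if (model$config$input_dim != ncol(graph$features))
    stop("checkpoint input_dim does not match graph features")
  if (length(split$test_idx) < 1L) stop("empty test split")
  emb <- vertex_embeddings(model, graph, "eval", edge_idx = edge_idx)
  P <- predict_edges(model, emb$H,
                     graph$edges[split$test_idx, , drop = FALSE])
  pred <- (P >= threshold) * 1
  colnames(pred) <- graph$categories$names
  truth <- graph$labels[split$test_idx, , drop = FALSE]
  metrics_report(pred, truth)
}

#' Export fused embeddings (and edge product features)
#'
#' Writes the n x h eval-mode vertex embeddings as a TSV
#' (`id` + h columns) for external visualisation (e.g. t-SNE), and
#' optionally the per-edge elementwise-product features together with
#' the edge labels.
#'
#' @param fit A `ppi_fit` or `ppi_model`.
#' @param graph The featured [protein_graph()].
#' @param path Output TSV for vertex embeddings.
#' @param edges_path Optional output TSV for edge product features and
#'   labels.
#' @return Invisibly, the written path(s).
#' @export
export_embeddings <- function(fit, graph, path, edges_path = NULL) {
  model <- if (inherits(fit, "ppi_fit")) fit$model else fit
  emb <- vertex_embeddings(model, graph, "eval")
  df <- data.frame(id = graph$protein_ids, emb$H, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  out <- path
  if (!is.null(edges_path)) {
    ed <- graph$edges
    Q <- emb$H[ed[, 1L], , drop = FALSE] * emb$H[ed[, 2L], , drop = FALSE]
    edf <- data.frame(id_a = graph$protein_ids[ed[, 1L]],
                      id_b = graph$protein_ids[ed[, 2L]], Q,
                      graph$labels, check.names = FALSE)
    utils::write.table(edf, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    out <- c(out, edges_path)
  }
  invisible(out)
}

CHECKPOINT_VERSION <- 1L

#' Save / load a model checkpoint
#'
#' A checkpoint bundles the model configuration, all parameter
#' tensors, batch-norm running statistics and a format version.
#'
#' @param fit A `ppi_fit` or `ppi_model`.
#' @param path Destination file.
#' @return `path` invisibly (save); a `ppi_model` (load).
#' @export
save_checkpoint <- function(fit, path) {
  model <- if (inherits(fit, "ppi_fit")) fit$model else fit
  saveRDS(list(version = CHECKPOINT_VERSION, config = model$config,
               params = model$params, state = model$state), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, CHECKPOINT_VERSION))
    stop("unsupported checkpoint version: ", obj$version)
  structure(list(config = obj$config, params = obj$params,
                 state = obj$state), class = "ppi_model")
}
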