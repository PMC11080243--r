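# Small shared training world: keep it tiny so the whole file runs in
# a few seconds.
tiny_world <- function(seed = 1) {
  g <- generate_ppi(easy_setting(n_proteins = 60), seed = seed)
  sp <- suppressWarnings(random_split(g, 0.2, seed))
  mc <- model_config(input_dim = ncol(g$features), hidden_dim = 16,
                     seed = seed)
  list(g = g, sp = sp, mc = mc)
}

test_that("frozen model early-stops at the patience boundary", {
  w <- tiny_world()
  # dropout off so the frozen model's epoch loss is exactly constant
  mc <- model_config(input_dim = ncol(w$g$features), hidden_dim = 16,
                     dropout_local = 0, dropout_global = 0, seed = 1)
  tc <- train_config(epochs = 50, batch_size = 4096, lr = 0,
                     patience = 1, seed = 1)
  fit <- train_ppi(w$g, w$sp, mc, tc)
  expect_equal(fit$stop_reason, "early_stop")
  expect_equal(nrow(fit$history), 2)  # epoch 1 sets best, epoch 2 stops
  expect_equal(fit$best_epoch, 1)
})

test_that("training is bitwise reproducible under a seed", {
  w <- tiny_world()
  tc <- train_config(epochs = 4, batch_size = 64, lr = 0.01, seed = 3)
  f1 <- train_ppi(w$g, w$sp, w$mc, tc)
  f2 <- train_ppi(w$g, w$sp, w$mc, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  tc2 <- train_config(epochs = 4, batch_size = 64, lr = 0.01, seed = 4)
  f3 <- train_ppi(w$g, w$sp, w$mc, tc2)
  expect_false(identical(f1$history$loss, f3$history$loss))
})

test_that("best checkpoint improves on epoch 1 and errors are guarded", {
  w <- tiny_world(2)
  tc <- train_config(epochs = 15, batch_size = 1024, lr = 0.01,
                     seed = 2)
  fit <- train_ppi(w$g, w$sp, w$mc, tc)
  expect_lte(fit$best_loss, fit$history$loss[1])
  expect_true(all(is.finite(fit$history$loss)))
  bare <- generate_ppi(easy_setting(n_proteins = 20), seed = 1)
  bare$features <- NULL
  expect_error(train_ppi(bare, w$sp, w$mc, tc), "no features")
  expect_error(train_ppi(w$g, w$sp,
                         model_config(input_dim = 99, hidden_dim = 16),
                         tc),
               "input_dim")
})

test_that("evaluation consistency: train >= test on the easy world", {
  ok <- 0
  for (seed in 1:3) {
    w <- tiny_world(seed)
    tc <- train_config(epochs = 40, batch_size = 1024, lr = 0.01,
                       seed = seed)
    fit <- train_ppi(w$g, w$sp, w$mc, tc)
    test_rep <- suppressWarnings(evaluate_ppi(fit, w$g, w$sp))
    train_split <- w$sp
    train_split$test_idx <- w$sp$train_idx
    train_rep <- suppressWarnings(evaluate_ppi(fit, w$g, train_split))
    if (train_rep$primary_f1 >= test_rep$primary_f1 - 0.02) ok <- ok + 1
  }
  expect_gte(ok, 2)
})

test_that("untrained model on balanced random labels sits near density", {
  # analytic expectation: an untrained head predicts ~at chance, so
  # micro-F1 is near the label density when predictions are random
  set.seed(50)
  g <- make_random_graph(80, 0.08)
  dens <- 0.5
  labs <- matrix(rbinom(n_edges(g) * 7, 1, dens), n_edges(g), 7)
  labs[rowSums(labs) == 0, 1] <- 1
  g <- protein_graph(g$protein_ids, g$edges, labs)
  X <- matrix(rnorm(80 * 8), 80, 8); rownames(X) <- g$protein_ids
  g <- attach_features(g, X)
  sp <- suppressWarnings(random_split(g, 0.3, 1))
  m <- ppi_model(model_config(input_dim = 8, hidden_dim = 16, seed = 2))
  rep_ <- suppressWarnings(evaluate_ppi(m, g, sp))
  expect_gt(rep_$primary_f1, dens - 0.25)
  expect_lt(rep_$primary_f1, dens + 0.25)
})

test_that("empty test split is rejected", {
  w <- tiny_world()
  sp <- w$sp
  sp$test_idx <- integer(0)
  expect_error(evaluate_ppi(ppi_model(w$mc), w$g, sp), "empty test")
})

test_that("embedding export writes n rows and is eval-stable", {
  w <- tiny_world()
  m <- ppi_model(w$mc)
  f <- withr::local_tempfile(); fe <- withr::local_tempfile()
  export_embeddings(m, w$g, f, fe)
  emb <- utils::read.table(f, sep = "\t")
  expect_equal(nrow(emb), n_proteins(w$g))
  expect_equal(ncol(emb), 1 + w$mc$hidden_dim)
  edges <- utils::read.table(fe, sep = "\t")
  expect_equal(nrow(edges), n_edges(w$g))
  f2 <- withr::local_tempfile()
  export_embeddings(m, w$g, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("checkpoints round-trip through files", {
  w <- tiny_world()
  tc <- train_config(epochs = 2, batch_size = 1024, seed = 5)
  fit <- train_ppi(w$g, w$sp, w$mc, tc)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, f)
  m2 <- load_checkpoint(f)
  expect_identical(m2$params, fit$model$params)
  r1 <- suppressWarnings(evaluate_ppi(fit, w$g, w$sp))
  r2 <- suppressWarnings(evaluate_ppi(m2, w$g, w$sp))
  expect_equal(r1$primary_f1, r2$primary_f1)
})

test_that("inductive mode hides test edges from message passing", {
  w <- tiny_world(4)
  tc <- train_config(epochs = 2, batch_size = 1024, seed = 4,
                     transductive = FALSE)
  fit <- train_ppi(w$g, w$sp, w$mc, tc)
  expect_s3_class(fit, "ppi_fit")
  # embeddings differ between full and train-only message passing
  e_full <- vertex_embeddings(fit$model, w$g)
  e_ind <- vertex_embeddings(fit$model, w$g,
                             edge_idx = w$sp$train_idx)
  expect_false(identical(e_full$H, e_ind$H))
})
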