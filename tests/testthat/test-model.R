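test_that("gin_update matches dense-matrix evaluation and edge cases", {
  set.seed(41)
  g <- make_random_graph(6, 0.5)
  X <- matrix(rnorm(6 * 3), 6, 3)
  prm <- list(W1 = matrix(rnorm(12), 3, 4), b1 = rnorm(4),
              W2 = matrix(rnorm(16), 4, 4), b2 = rnorm(4), eps = 0.3)
  out <- gin_update(X, g, prm)
  A <- matrix(0, 6, 6)
  for (r in seq_len(n_edges(g))) {
    A[g$edges[r, 1], g$edges[r, 2]] <- 1
    A[g$edges[r, 2], g$edges[r, 1]] <- 1
  }
  S <- (A + (1 + prm$eps) * diag(6)) %*% X
  ref <- pmax(sweep(pmax(sweep(S %*% prm$W1, 2, prm$b1, "+"), 0) %*%
                      prm$W2, 2, prm$b2, "+"), 0)
  expect_equal(out, ref, tolerance = 1e-12)

  # no edges, eps = 0: pure per-vertex MLP
  iso <- protein_graph(c("a", "b"), matrix(integer(0), 0, 2),
                       matrix(numeric(0), 0, 7))
  prm0 <- prm; prm0$eps <- 0
  o2 <- gin_update(X[1:2, ], iso, prm0)
  expect_equal(o2[1, ], gin_update(X[1, , drop = FALSE],
                                   protein_graph("a",
                                                 matrix(integer(0), 0, 2),
                                                 matrix(numeric(0), 0, 7)),
                                   prm0)[1, ])

  # vertex-transitive graph with identical features -> identical rows
  cyc <- protein_graph(paste0("c", 1:5),
                       cbind(1:5, c(2:5, 1)),
                       matrix(rep(c(1, rep(0, 6)), 5), 5, 7,
                              byrow = TRUE))
  same <- gin_update(matrix(1, 5, 3), cyc, prm)
  expect_equal(max(apply(same, 2, function(cl) diff(range(cl)))), 0)
})

test_that("edge predictions are endpoint-order invariant and in (0,1)", {
  fx <- make_model_fixture()
  emb <- vertex_embeddings(fx$model, fx$graph)
  ed <- fx$graph$edges
  p1 <- predict_edges(fx$model, emb$H, ed)
  p2 <- predict_edges(fx$model, emb$H, ed[, 2:1])
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_true(all(is.finite(emb$H)))
  expect_error(predict_edges(fx$model, emb$H, rbind(c(1, 999))),
               "invalid")
  # per-edge loop oracle for the head
  prm <- fx$model$params
  for (r in sample(nrow(ed), 5)) {
    q <- emb$H[ed[r, 1], ] * emb$H[ed[r, 2], ]
    z <- drop(q %*% prm$hW) + prm$hb
    expect_equal(unname(p1[r, ]), unname(1 / (1 + exp(-z))),
                 tolerance = 1e-9)
  }
})

test_that("end-to-end permutation equivariance of edge probabilities", {
  fx <- make_model_fixture(n = 14, seed = 6)
  g <- fx$graph
  emb <- vertex_embeddings(fx$model, g)
  p0 <- predict_edges(fx$model, emb$H, g$edges)
  set.seed(99)
  perm <- sample.int(n_proteins(g))
  inv <- order(perm)
  g2 <- protein_graph(g$protein_ids[inv], matrix(perm[g$edges], ncol = 2),
                      g$labels, g$categories,
                      features = g$features[inv, , drop = FALSE])
  emb2 <- vertex_embeddings(fx$model, g2)
  p2 <- predict_edges(fx$model, emb2$H, matrix(perm[g$edges], ncol = 2))
  expect_equal(p0, p2, tolerance = 1e-6)
})

test_that("batched local encoder equals the unbatched per-egonet oracle", {
  for (seed in c(5, 8)) {
    fx <- make_model_fixture(n = 15, seed = seed)
    emb <- vertex_embeddings(fx$model, fx$graph)
    ref <- oracle_local_encoder(fx$model, fx$graph)
    expect_equal(unname(emb$local), unname(ref), tolerance = 1e-6)
  }
  # 5-vertex path with fixed small weights
  path <- make_path_graph(5)
  path <- attach_features(path, {
    X <- matrix(seq_len(10) / 10, 5, 2)
    rownames(X) <- path$protein_ids
    X
  })
  cfg <- model_config(input_dim = 2, hidden_dim = 6, k = 1,
                      dropout_local = 0, dropout_global = 0, seed = 1)
  m <- ppi_model(cfg)
  m$params <- lapply(m$params, function(x) x + 0.01)
  expect_equal(unname(vertex_embeddings(m, path)$local),
               unname(oracle_local_encoder(m, path)), tolerance = 1e-6)
})

test_that("zero gate weights give a flat 0.5 gate on the sum branch", {
  fx <- make_model_fixture(n = 12, seed = 7)
  m <- fx$model
  m$params$aW1[] <- 0; m$params$ab1[] <- 0
  m$params$aW2[] <- 0; m$params$ab2[] <- 0
  g <- fx$graph
  ctx <- ppitype:::mp_context(g, m$config)
  fw <- ppitype:::forward_vertex(m, g$features, ctx, "eval")
  l <- fw$cache$l
  expect_equal(unique(as.numeric(l$gs$g)), 0.5)
  # subgraph branch = 0.5 * sum over members of kernel embeddings
  ref <- 0.5 * as.matrix(ctx$Pcen %*% l$L2)
  expect_equal(unname(l$h_sub), unname(ref), tolerance = 1e-12)
})

test_that("fuse concatenates and ablation paths change head width", {
  a <- matrix(1:6, 3, 2); b <- matrix(0, 3, 2)
  expect_equal(dim(fuse(a, b)), c(3, 4))
  expect_equal(fuse(a, b)[, 1:2], a)
  expect_error(fuse(a, matrix(0, 2, 2)), "mismatch")
  for (p in c("global", "local", "both")) {
    fx <- make_model_fixture(n = 10, seed = 3, paths = p)
    emb <- vertex_embeddings(fx$model, fx$graph)
    expect_equal(ncol(emb$H), if (p == "both") 8 else 4)
    if (p == "global") expect_null(emb$local)
    if (p == "local") expect_null(emb$global)
  }
})

test_that("k = 0 reduces the local branch to a doubled gated MLP", {
  fx <- make_model_fixture(n = 8, seed = 4, k = 0, paths = "local")
  g <- fx$graph
  m <- fx$model
  ctx <- ppitype:::mp_context(g, m$config)
  fw <- ppitype:::forward_vertex(m, g$features, ctx, "eval")
  l <- fw$cache$l
  expect_equal(l$pre, 2 * (l$gs$g * l$L2), tolerance = 1e-12)
})

test_that("full backprop matches finite differences", {
  fx <- make_model_fixture(n = 12, seed = 10)
  g <- fx$graph; m <- fx$model
  ctx <- ppitype:::mp_context(g, m$config)
  ed <- g$edges; Y <- g$labels
  prm <- asl_params(1, 0, 0.05)
  lossf <- function(model) {
    fw <- ppitype:::forward_vertex(model, g$features, ctx, "train")
    asl_loss(predict_edges(model, fw$H, ed), Y, prm)
  }
  fw <- ppitype:::forward_vertex(m, g$features, ctx, "train")
  Hi <- fw$H[ed[, 1], ]; Hj <- fw$H[ed[, 2], ]
  Q <- Hi * Hj
  Z <- sweep(Q %*% m$params$hW, 2, m$params$hb, "+")
  P <- pmin(pmax(1 / (1 + exp(-Z)), 1e-8), 1 - 1e-8)
  dZ <- ppitype:::asl_grad_p(P, Y, prm) / length(P) * P * (1 - P)
  dH <- ppitype:::scatter_edge_grad(dZ, m, Q, Hi, Hj, ed, nrow(fw$H))
  grads <- ppitype:::backward_vertex(m, ctx, fw$cache, dH)
  hd <- attr(dH, "head")
  grads$hW <- hd$hW; grads$hb <- hd$hb
  h <- 1e-5
  set.seed(1)
  for (nm in names(m$params)) {
    v <- m$params[[nm]]
    pick <- if (length(v) <= 4) seq_along(v)
            else sort(sample.int(length(v), 4))
    for (i in pick) {
      mp <- m; mp$params[[nm]][i] <- v[i] + h
      mm <- m; mm$params[[nm]][i] <- v[i] - h
      fd <- (lossf(mp) - lossf(mm)) / (2 * h)
      expect_equal(unname(grads[[nm]][i]), fd, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("batchnorm behaves as batchnorm in train mode", {
  fx <- make_model_fixture(n = 30, seed = 12)
  m <- fx$model
  ctx <- ppitype:::mp_context(fx$graph, m$config)
  fw <- ppitype:::forward_vertex(m, fx$graph$features, ctx, "train")
  # train-mode output columns: mean beta, sd ~ gamma
  expect_equal(unname(colMeans(fw$global)), unname(m$params$gBeta),
               tolerance = 1e-8)
  biased_sd <- sqrt(colMeans(sweep(fw$global, 2,
                                   colMeans(fw$global))^2))
  # biased sd of the output is |gamma| shrunk by the BN epsilon
  va <- fw$cache$g$bn$va
  expect_equal(unname(biased_sd),
               unname(abs(m$params$gGamma)) * sqrt(va / (va + 1e-5)),
               tolerance = 1e-6)
  # eval mode deterministic
  e1 <- vertex_embeddings(m, fx$graph)
  e2 <- vertex_embeddings(m, fx$graph)
  expect_identical(e1$H, e2$H)
})
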