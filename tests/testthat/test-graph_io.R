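test_that("read_interactions merges directions and modes into multi-label edges", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\tbinding", "B\tA\tactivation", "A\tC\treaction"), f)
  g <- read_interactions(f)
  expect_equal(n_proteins(g), 3)
  expect_equal(n_edges(g), 2)
  expect_equal(g$protein_ids, c("A", "B", "C"))
  ab <- which(g$edges[, 1] == 1 & g$edges[, 2] == 2)
  expect_equal(unname(g$labels[ab, ]), c(0, 1, 0, 1, 0, 0, 0))
})

test_that("read_interactions handles separators, headers, errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("item_id_a,item_id_b,mode", "A,B,Binding", "A,B,binding",
               "C,C,reaction", "B,C,ptmod"), f)
  expect_warning(g <- read_interactions(f), "self-interaction")
  expect_equal(n_edges(g), 2)          # duplicate row collapsed
  expect_equal(sum(g$labels), 2)

  bad <- withr::local_tempfile()
  writeLines(c("A\tB\tbinding", "A\tC\tfrobnication"), bad)
  expect_error(read_interactions(bad), "frobnication.*line 2")

  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  expect_error(read_interactions(empty), "no interactions parsed")
})

test_that("read_interactions is invariant to row shuffling", {
  set.seed(11)
  g0 <- generate_ppi(easy_setting(n_proteins = 40), seed = 2)
  f <- withr::local_tempfile()
  write_interactions(g0, f)
  rows <- readLines(f)
  shuffled <- withr::local_tempfile()
  writeLines(c(rows[1], sample(rows[-1])), shuffled)
  g1 <- read_interactions(f)
  g2 <- read_interactions(shuffled)
  key <- function(g) {
    pairs <- cbind(g$protein_ids[g$edges[, 1]], g$protein_ids[g$edges[, 2]])
    k <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    rownames(g$labels) <- k
    g$labels[order(k), ]
  }
  expect_equal(key(g1), key(g2))
})

test_that("interaction round-trip preserves the graph", {
  g0 <- generate_ppi(hard_setting(n_proteins = 50), seed = 3)
  f <- withr::local_tempfile()
  write_interactions(g0, f)
  g1 <- read_interactions(f)
  # isolated proteins cannot survive an edge-list format; every
  # protein with >= 1 edge must round-trip
  connected <- which(vertex_degrees(g0) > 0)
  expect_setequal(g1$protein_ids, g0$protein_ids[connected])
  perm <- match(g0$protein_ids, g1$protein_ids)
  remap <- cbind(pmin(perm[g0$edges[, 1]], perm[g0$edges[, 2]]),
                 pmax(perm[g0$edges[, 1]], perm[g0$edges[, 2]]))
  ord0 <- order(remap[, 1], remap[, 2])
  ord1 <- order(g1$edges[, 1], g1$edges[, 2])
  expect_equal(remap[ord0, ], g1$edges[ord1, ])
  expect_equal(unname(g0$labels[ord0, ]), unname(g1$labels[ord1, ]))
})

test_that("attach_features aligns, errors on missing, warns on extra", {
  g <- make_path_graph(3)
  X <- matrix(1:12 / 10, 3, 4,
              dimnames = list(c("p2", "p3", "p1"), NULL))
  g2 <- attach_features(g, X)
  expect_equal(dim(g2$features), c(3, 4))
  expect_equal(g2$features["p2", ], X["p2", ])
  expect_equal(rownames(g2$features), g$protein_ids)

  expect_error(attach_features(g, X[1:2, , drop = FALSE]),
               "missing protein.*p1")
  X4 <- rbind(X, p9 = rep(0, 4))
  expect_warning(attach_features(g, X4), "not in graph")

  f <- withr::local_tempfile()
  write_feature_table(X, f)
  g3 <- attach_features(g, f)
  expect_equal(g3$features, g2$features)
})

test_that("category_statistics reproduces printed occupation ratios", {
  # published per-category sample counts for two curated PPI datasets
  shs27k <- c(3164, 4017, 1303, 3297, 1407, 3492, 687)
  shs148k <- c(18067, 23448, 9336, 18910, 8987, 19871, 3419)
  r27 <- occupation_ratios(shs27k)
  r148 <- occupation_ratios(shs148k)
  expect_equal(round(100 * r27, 2),
               c(18.22, 23.13, 7.50, 18.98, 8.10, 20.11, 3.96))
  expect_equal(round(100 * r148, 2),
               c(17.71, 22.98, 9.15, 18.53, 8.81, 19.47, 3.35))
  expect_equal(sum(r27), 1, tolerance = 1e-9)
})

test_that("category_statistics on graphs: single category and totals", {
  g <- make_star_graph(4)     # all edges category 1
  st <- category_statistics(g)
  expect_equal(st$occupation_ratio, c(1, rep(0, 6)))
  g2 <- generate_ppi(easy_setting(n_proteins = 50), seed = 4)
  st2 <- category_statistics(g2)
  expect_equal(st2$count, unname(colSums(g2$labels)))
  expect_equal(sum(st2$occupation_ratio), 1, tolerance = 1e-9)
})

test_that("baseline sequence encoder is deterministic and class-driven", {
  seqs <- c(a = "MKVLAAGG", b = "MKVLAAGG", c = "WWPPRRHH")
  cfg <- seq_encoder_config(dim = 12, seed = 3)
  enc <- encode_sequences_baseline(seqs, cfg)
  expect_equal(dim(enc), c(3, 12))
  expect_equal(enc["a", ], enc["b", ])
  expect_false(isTRUE(all.equal(enc["a", ], enc["c", ])))
  # oracle: relabel residues and permute the class table rows the same
  # way -> encodings must be identical
  tab <- aa_class_table()
  perm <- setNames(rev(rownames(tab)), rownames(tab))
  tab2 <- tab
  rownames(tab2) <- unname(perm[rownames(tab)])
  relabel <- function(s) paste(perm[strsplit(s, "")[[1]]], collapse = "")
  cfg2 <- seq_encoder_config(dim = 12, seed = 3, class_table = tab2)
  enc2 <- encode_sequences_baseline(vapply(seqs, relabel, ""), cfg2)
  expect_equal(unname(enc), unname(enc2))
  expect_error(encode_sequences_baseline(c(x = "")), "empty sequence")
})

test_that("FASTA fixtures parse through the encoder", {
  g <- generate_ppi(easy_setting(n_proteins = 10), seed = 1)
  dir <- withr::local_tempdir()
  paths <- write_fixture(g, dir)
  enc <- encode_sequences_baseline(paths[["fasta"]],
                                   seq_encoder_config(dim = 8))
  expect_equal(dim(enc), c(10, 8))
  expect_equal(rownames(enc), g$protein_ids)
})
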