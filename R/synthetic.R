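#' Specification for a synthetic PPI-like multi-label graph
#'
#' Describes a stochastic-block-model world with planted, learnable
#' category structure: proteins belong to latent functional groups,
#' edges appear with higher probability within groups, each edge's
#' category labels are drawn from a per-group-pair probability rule
#' (conditioned on at least one positive, matching the dataset
#' invariant), and vertex features are the group centroid plus Gaussian
#' noise.  The generator therefore emulates the *structure* of curated
#' PPI action datasets — a sparse undirected graph, multi-label edges
#' over seven imbalanced categories, and features that carry
#' category-predictive signal — not their biology.
#'
#' @param n_proteins Number of proteins.
#' @param n_groups Number of latent functional groups.
#' @param edge_prob_within,edge_prob_between Edge probabilities inside
#'   and across groups.
#' @param category_rule Array of dimension
#'   `(n_groups, n_groups, n_categories)` giving, for each group pair,
#'   the per-category label probabilities (symmetrised internally).
#'   `NULL` derives a uniform rule from `imbalance_target`.
#' @param feature_dim Vertex feature length.
#' @param feature_noise_sd Standard deviation of the feature noise
#'   around the group centroid.
#' @param imbalance_target Optional per-category occupation-ratio
#'   targets (summing to 1) used when `category_rule` is `NULL`;
#'   probabilities are scaled so edges carry `labels_per_edge`
#'   categories on average.
#' @param labels_per_edge Mean number of labels per edge for the
#'   derived rule.
#' @param degree_exponent Optional power-law exponent producing
#'   heterogeneous expected degrees (`NULL` = homogeneous).
#' @param seed Default seed used by [generate_ppi()].
#' @param categories A [category_space()].
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_proteins = 300L, n_groups = 4L,
                       edge_prob_within = 0.15,
                       edge_prob_between = 0.02,
                       category_rule = NULL, feature_dim = 32L,
                       feature_noise_sd = 0.2,
                       imbalance_target = NULL,
                       labels_per_edge = 1.5,
                       degree_exponent = NULL, seed = 1L,
                       categories = category_space()) {
  stopifnot(n_proteins >= 2L, n_groups >= 1L,
            edge_prob_within >= 0, edge_prob_within <= 1,
            edge_prob_between >= 0, edge_prob_between <= 1,
            feature_dim >= 1L, feature_noise_sd >= 0)
  t <- categories$t
  if (is.null(category_rule)) {
    target <- imbalance_target %||% rep(1 / t, t)
    if (length(target) != t || any(target < 0))
      stop("imbalance_target must be ", t, " non-negative ratios")
    target <- target / sum(target)
    p <- pmin(target * labels_per_edge, 0.95)
    category_rule <- array(rep(p, each = n_groups^2),
                           dim = c(n_groups, n_groups, t))
  }
  stopifnot(all(dim(category_rule) == c(n_groups, n_groups, t)),
            all(category_rule >= 0), all(category_rule <= 1))
  # symmetrise: unordered group pairs share one probability vector
  for (c in seq_len(t))
    category_rule[, , c] <- (category_rule[, , c] +
                               t(category_rule[, , c])) / 2
  if (all(apply(category_rule, c(1, 2), sum) == 0))
    stop("degenerate rule: no category can ever be drawn")
  structure(list(n_proteins = as.integer(n_proteins),
                 n_groups = as.integer(n_groups),
                 edge_prob_within = edge_prob_within,
                 edge_prob_between = edge_prob_between,
                 category_rule = category_rule,
                 feature_dim = as.integer(feature_dim),
                 feature_noise_sd = feature_noise_sd,
                 degree_exponent = degree_exponent,
                 seed = as.integer(seed), categories = categories),
            class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat("<synth_spec> n=", x$n_proteins, " groups=", x$n_groups,
      " p_in=", x$edge_prob_within, " p_out=", x$edge_prob_between,
      " d=", x$feature_dim, " noise=", x$feature_noise_sd, "\n",
      sep = "")
  invisible(x)
}

#' Generate a synthetic multi-label PPI graph
#'
#' Samples a graph from a [synth_spec()]: stochastic-block-model edges,
#' per-edge multi-label categories from the group-pair rule
#' (conditioned on at least one positive by drawing one category from
#' the normalised rule when the independent draws all miss), and
#' centroid-plus-noise features.  The latent group assignment and the
#' rule are attached as attributes `"groups"` and `"rule"` so tests can
#' use the ground truth as an oracle.
#'
#' @param spec A [synth_spec()].
#' @param seed Seed (defaults to `spec$seed`); the same
#'   `(spec, seed)` always yields the identical graph.
#' @return A featured [protein_graph()].
#' @export
generate_ppi <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_proteins; G <- spec$n_groups
  t <- spec$categories$t
  with_seed(seed, {
    groups <- sort(rep_len(seq_len(G), n))
    idx <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
    gi <- groups[idx[, 1L]]; gj <- groups[idx[, 2L]]
    p_edge <- ifelse(gi == gj, spec$edge_prob_within,
                     spec$edge_prob_between)
    if (!is.null(spec$degree_exponent)) {
      w <- (seq_len(n) / n)^(-spec$degree_exponent)
      w <- w / mean(w)
      p_edge <- pmin(p_edge * w[idx[, 1L]] * w[idx[, 2L]], 1)
    }
    keep <- stats::runif(length(p_edge)) < p_edge
    if (!any(keep)) stop("degenerate spec: no edges were generated")
    edges <- cbind(idx[keep, 1L], idx[keep, 2L])
    gi <- gi[keep]; gj <- gj[keep]
    e <- nrow(edges)
    probs <- matrix(0, e, t)
    for (c in seq_len(t))
      probs[, c] <- spec$category_rule[cbind(gi, gj, c)]
    labels <- (matrix(stats::runif(e * t), e, t) < probs) * 1
    empty <- which(rowSums(labels) == 0)
    for (r in empty) {
      pr <- probs[r, ]
      if (sum(pr) == 0) pr <- rep(1, t)
      labels[r, sample.int(t, 1L, prob = pr)] <- 1
    }
    centroids <- matrix(stats::rnorm(G * spec$feature_dim), G,
                        spec$feature_dim)
    X <- centroids[groups, , drop = FALSE] +
      matrix(stats::rnorm(n * spec$feature_dim,
                          sd = spec$feature_noise_sd), n,
             spec$feature_dim)
    g <- protein_graph(sprintf("P%04d", seq_len(n)), edges, labels,
                       spec$categories, features = X)
    attr(g, "groups") <- groups
    attr(g, "rule") <- spec$category_rule
    attr(g, "spec") <- spec
    g
  })
}

#' Preset synthetic worlds
#'
#' `easy_setting()` is a strongly separable world: low feature noise
#' and a *deterministic* category rule (each unordered group pair maps
#' to a fixed set of one or two categories), so a working model should
#' reach high test micro-F1.  `hard_setting()` has overlapping
#' probabilistic rules built on an imbalanced category base (occupation
#' ratios roughly matching curated PPI action data) plus strong feature
#' noise, so headroom between losses and architectures becomes
#' visible.
#'
#' @param n_proteins Number of proteins (defaults: 300 easy, 240
#'   hard).
#' @param seed Default generation seed stored in the spec.
#' @return A [synth_spec()].
#' @export
easy_setting <- function(n_proteins = 300L, seed = 1L) {
  G <- 4L; t <- 7L
  rule <- array(0, dim = c(G, G, t))
  assign_pair <- function(i, j, cats) {
    for (c in cats) {
      rule[i, j, c] <<- 1
      rule[j, i, c] <<- 1
    }
  }
  assign_pair(1, 1, 1); assign_pair(1, 2, 2); assign_pair(1, 3, 3)
  assign_pair(1, 4, 4); assign_pair(2, 2, 5); assign_pair(2, 3, 6)
  assign_pair(2, 4, 7); assign_pair(3, 3, c(1, 2))
  assign_pair(3, 4, c(3, 5)); assign_pair(4, 4, c(4, 6))
  synth_spec(n_proteins = n_proteins, n_groups = G,
             edge_prob_within = 0.15, edge_prob_between = 0.02,
             category_rule = rule, feature_dim = 32L,
             feature_noise_sd = 0.2, seed = seed)
}

#' @rdname easy_setting
#' @export
hard_setting <- function(n_proteins = 240L, seed = 1L) {
  G <- 4L; t <- 7L
  # occupation-ratio profile of curated PPI action data; the
  # pair-specific boost is multiplicative so rare categories stay rare
  base <- c(0.18, 0.23, 0.08, 0.19, 0.08, 0.20, 0.04)
  rule <- array(rep(pmin(base * 1.5, 0.95), each = G^2),
                dim = c(G, G, t))
  for (i in seq_len(G)) for (j in seq_len(G)) {
    boost <- ((i + j) %% t) + 1L
    rule[i, j, boost] <- min(rule[i, j, boost] * 2.5, 0.95)
  }
  synth_spec(n_proteins = n_proteins, n_groups = G,
             edge_prob_within = 0.15, edge_prob_between = 0.03,
             category_rule = rule, feature_dim = 32L,
             feature_noise_sd = 1.0, seed = seed)
}

#' Write a synthetic graph as a file fixture
#'
#' Writes `interactions.tsv`, `features.tsv` and a deterministic
#' `sequences.fasta` stub (synthetic sequences, labelled as such) into
#' a directory so the file-parsing path can be exercised end to end.
#' Reading the files back with [read_interactions()] and
#' [attach_features()] reproduces the graph exactly.
#'
#' @param graph A featured [protein_graph()].
#' @param dir Output directory (created if needed).
#' @param seq_seed Seed for the synthetic FASTA sequences.
#' @return Invisibly, the three file paths.
#' @export
write_fixture <- function(graph, dir, seq_seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ip <- file.path(dir, "interactions.tsv")
  fp <- file.path(dir, "features.tsv")
  sp <- file.path(dir, "sequences.fasta")
  write_interactions(graph, ip)
  write_feature_table(graph$features, fp)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
  with_seed(seq_seed, {
    lines <- unlist(lapply(graph$protein_ids, function(id) {
      c(paste0(">", id, " synthetic"),
        paste(sample(aa, 60L, replace = TRUE), collapse = ""))
    }))
    writeLines(lines, sp)
  })
  invisible(c(interactions = ip, features = fp, fasta = sp))
}
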