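#' Amino-acid class table for the baseline sequence encoder
#'
#' A 13-dimensional per-residue binary encoding: the first 5 columns are
#' a one-hot co-occurrence grouping of the 20 standard amino acids, the
#' remaining 8 columns are multi-hot physicochemical classes
#' (hydrophobic, aromatic, polar, positively charged, negatively
#' charged, small, aliphatic, sulfur-containing).  The exact grouping is
#' a documented package choice and can be overridden by supplying any
#' matrix with amino-acid letters as row names; non-standard letters are
#' mapped to an all-zero catch-all row.
#'
#' @return A 20 x 13 binary matrix with amino-acid letters as row names.
#' @export
aa_class_table <- function() {
  aa <- c("A", "G", "V", "I", "L", "F", "P", "Y", "M", "T",
          "S", "H", "N", "Q", "W", "R", "K", "D", "E", "C")
  cooc <- list(c("A", "G", "V"),
               c("I", "L", "F", "P"),
               c("Y", "M", "T", "S"),
               c("H", "N", "Q", "W"),
               c("R", "K", "D", "E", "C"))
  prop <- list(hydrophobic = c("A", "V", "L", "I", "M", "F", "W"),
               aromatic    = c("F", "Y", "W", "H"),
               polar       = c("S", "T", "N", "Q", "Y", "C"),
               positive    = c("K", "R", "H"),
               negative    = c("D", "E"),
               small       = c("A", "G", "S", "C", "T"),
               aliphatic   = c("A", "V", "L", "I", "G"),
               sulfur      = c("C", "M"))
  tab <- matrix(0, length(aa), 13L,
                dimnames = list(aa, c(paste0("cooc", 1:5), names(prop))))
  for (i in seq_along(cooc)) tab[cooc[[i]], i] <- 1
  for (i in seq_along(prop)) tab[prop[[i]], 5L + i] <- 1
  tab
}

#' Baseline sequence encoder configuration
#'
#' @param dim Output feature dimension per protein.
#' @param hidden Width of the convolution channel.
#' @param seed Seed for the (fixed, random) projection weights; the
#'   encoder is deterministic given the seed.
#' @param class_table Per-residue class encoding matrix (rows named by
#'   amino-acid letter); defaults to [aa_class_table()].
#' @return A list of class `seq_encoder_config`.
#' @export
seq_encoder_config <- function(dim = 64L, hidden = 32L, seed = 1L,
                               class_table = aa_class_table()) {
  stopifnot(dim >= 1L, hidden >= 1L)
  structure(list(dim = as.integer(dim), hidden = as.integer(hidden),
                 seed = as.integer(seed),
                 class_table = as.matrix(class_table)),
            class = "seq_encoder_config")
}

#' Encode protein sequences with a fixed random convolutional baseline
#'
#' A deliberately simple, training-free stand-in for pretrained protein
#' embeddings: each residue is mapped to its 13-dimensional class vector
#' (see [aa_class_table()]), a width-3 one-layer convolution with seeded
#' random weights and ReLU is slid over the sequence, channels are
#' mean-pooled over positions, and a seeded linear map produces the
#' configured output dimension.  Identical sequences give identical
#' vectors; the output depends on residues only through their class
#' vectors.
#'
#' @param fasta Path to a FASTA file, or a named character vector of
#'   sequences.
#' @param config A [seq_encoder_config()].
#' @return Numeric matrix, one row per sequence (row names = FASTA
#'   names), `config$dim` columns.
#' @export
encode_sequences_baseline <- function(fasta, config = seq_encoder_config()) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L &&
              file.exists(fasta)) read_fasta(fasta) else fasta
  if (length(seqs) == 0L) stop("no sequences to encode")
  if (any(!nzchar(seqs))) stop("empty sequence")
  tab <- config$class_table
  p <- ncol(tab)
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(config$seed)
    expr
  }
  weights <- withr_seed({
    list(wc = matrix(stats::rnorm(3L * p * config$hidden,
                                  sd = 1 / sqrt(3 * p)),
                     3L * p, config$hidden),
         bc = stats::rnorm(config$hidden, sd = 0.1),
         wo = matrix(stats::rnorm(config$hidden * config$dim,
                                  sd = 1 / sqrt(config$hidden)),
                     config$hidden, config$dim),
         bo = stats::rnorm(config$dim, sd = 0.1))
  })
  out <- t(vapply(seqs, function(s) {
    res <- strsplit(toupper(s), "")[[1L]]
    idx <- match(res, rownames(tab))
    enc <- matrix(0, length(res), p)        # catch-all rows stay zero
    known <- !is.na(idx)
    enc[known, ] <- tab[idx[known], , drop = FALSE]
    padded <- rbind(0, enc, 0)              # zero padding, width-3 window
    l <- length(res)
    win <- cbind(padded[seq_len(l), , drop = FALSE],
                 padded[seq_len(l) + 1L, , drop = FALSE],
                 padded[seq_len(l) + 2L, , drop = FALSE])
    h <- pmax(sweep(win %*% weights$wc, 2L, weights$bc, "+"), 0)
    drop(colMeans(h) %*% weights$wo) + weights$bo
  }, numeric(config$dim)))
  rownames(out) <- names(seqs)
  out
}

# Minimal FASTA access via Biostrings (fails clearly on non-FASTA).
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("cannot read FASTA ", path,
                                           ": ", conditionMessage(e)))
  if (length(set) == 0L) stop("no sequences in ", path)
  s <- as.character(set)
  names(s) <- sub("\\s.*$", "", names(set))
  s
}
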