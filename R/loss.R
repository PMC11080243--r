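#' Asymmetric loss parameters
#'
#' The asymmetric loss (ASL) decouples the focal focusing exponent into
#' a positive part `gamma_pos` and a negative part `gamma_neg`, and
#' shifts negative-cell probabilities by a margin `m` so that easy
#' negatives (`p <= m`) contribute zero loss.  Defaults follow the
#' recommended setting for imbalanced PPI categories: `gamma_pos = 1`,
#' `gamma_neg = 0`, `margin = 0.05`.
#'
#' @param gamma_pos Positive focusing exponent, `>= 0`.
#' @param gamma_neg Negative focusing exponent, `>= 0`.
#' @param margin Probability margin `m` in `[0, 1)`.
#' @return A list of class `asl_params`.
#' @export
asl_params <- function(gamma_pos = 1, gamma_neg = 0, margin = 0.05) {
  stopifnot(gamma_pos >= 0, gamma_neg >= 0, margin >= 0, margin < 1)
  structure(list(gamma_pos = gamma_pos, gamma_neg = gamma_neg,
                 margin = margin), class = "asl_params")
}

# Clamp probabilities away from {0, 1} before taking logs.
PROB_EPS <- 1e-8

#' Asymmetric loss for multi-label classification
#'
#' Per-cell loss
#' `-[ y (1-p)^g+ log p + (1-y) pm^g- log(1-pm) ]` with
#' `pm = max(p - m, 0)` and the convention `0^0 = 1`.  With
#' `gamma_pos = gamma_neg = 0` and `m = 0` this is exactly binary
#' cross-entropy; with equal exponents and `m = 0` it is the focal
#' loss.  Probabilities are clamped to `[1e-8, 1 - 1e-8]`.
#'
#' @param probabilities Numeric matrix (or vector) of predicted
#'   probabilities in (0, 1).
#' @param labels Binary matrix (or vector) of the same shape.
#' @param params An [asl_params()] object.
#' @param reduction `"mean"` (default) or `"sum"` over all cells.
#' @return Scalar non-negative loss.
#' @export
asl_loss <- function(probabilities, labels, params = asl_params(),
                     reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  pieces <- asl_pieces(probabilities, labels, params)
  if (reduction == "mean") mean(pieces) else sum(pieces)
}

# Per-cell ASL values (matrix-shaped).
asl_pieces <- function(p, y, params) {
  if (length(p) != length(y)) stop("shape mismatch between p and y")
  if (any(p <= 0) || any(p >= 1))
    stop("probabilities must lie strictly in (0, 1); clamp with eps")
  p <- pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)
  pm <- pmax(p - params$margin, 0)
  # 0^0 = 1 must hold for gamma = 0 so that BCE is recovered exactly
  pow <- function(base, expo) if (expo == 0) 1 else base^expo
  pos <- -pow(1 - p, params$gamma_pos) * log(p)
  neg <- -pow(pm, params$gamma_neg) * log1p(-pm)
  y * pos + (1 - y) * neg
}

# d(loss)/dp per cell for the *sum* reduction; the training code scales
# by 1/(E*t) for the mean.  At p = m the negative branch takes the flat
# subgradient 0.
asl_grad_p <- function(p, y, params) {
  p <- pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)
  gp <- params$gamma_pos; gn <- params$gamma_neg; m <- params$margin
  pm <- pmax(p - m, 0)
  dpos <- if (gp == 0) -1 / p
          else gp * (1 - p)^(gp - 1) * log(p) - (1 - p)^gp / p
  dneg <- if (gn == 0) rep_len(1, length(p)) / (1 - pm)
          else -gn * pm^(gn - 1) * log1p(-pm) + pm^gn / (1 - pm)
  dneg[p <= m] <- 0  # flat subgradient below the margin, including p = m
  y * dpos + (1 - y) * dneg
}

#' Focal loss
#'
#' Symmetric special case of [asl_loss()]: equal focusing exponent for
#' positive and negative cells and no probability margin.  `gamma = 0`
#' recovers binary cross-entropy.
#'
#' @inheritParams asl_loss
#' @param gamma Focusing exponent, `>= 0`.
#' @return Scalar non-negative loss.
#' @export
focal_loss <- function(probabilities, labels, gamma = 2,
                       reduction = c("mean", "sum")) {
  asl_loss(probabilities, labels,
           asl_params(gamma_pos = gamma, gamma_neg = gamma, margin = 0),
           reduction = match.arg(reduction))
}

#' Binary cross-entropy loss
#'
#' Convenience wrapper: [asl_loss()] with all asymmetry switched off.
#'
#' @inheritParams asl_loss
#' @return Scalar non-negative loss.
#' @export
bce_loss <- function(probabilities, labels,
                     reduction = c("mean", "sum")) {
  asl_loss(probabilities, labels,
           asl_params(gamma_pos = 0, gamma_neg = 0, margin = 0),
           reduction = match.arg(reduction))
}

# Resolve a loss spec ("asl" | "bce" | "focal" + params) used by
# train_config into value/gradient closures on probability matrices.
resolve_loss <- function(loss = c("asl", "bce", "focal"),
                         params = asl_params(), gamma = 2) {
  loss <- match.arg(loss)
  prm <- switch(loss,
    asl = params,
    bce = asl_params(0, 0, 0),
    focal = asl_params(gamma, gamma, 0))
  list(name = loss, params = prm,
       value = function(p, y) mean(asl_pieces(p, y, prm)),
       grad = function(p, y) asl_grad_p(p, y, prm) / length(p))
}
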