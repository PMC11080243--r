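#' Per-category confusion counts
#'
#' Cell-wise true/false positive/negative counts for each category
#' column of a pair of binary prediction and truth matrices.
#'
#' @param pred Binary E x t matrix of predicted labels.
#' @param truth Binary E x t matrix of true labels.
#' @return Data frame with one row per category and columns `TP`, `FP`,
#'   `FN`, `TN`, `support` (`= TP + FN`).
#' @export
confusion_counts <- function(pred, truth) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!all(dim(pred) == dim(truth))) stop("shape mismatch")
  tp <- colSums(pred == 1 & truth == 1)
  fp <- colSums(pred == 1 & truth == 0)
  fn <- colSums(pred == 0 & truth == 1)
  tn <- colSums(pred == 0 & truth == 0)
  data.frame(category = colnames(truth) %||% paste0("C", seq_len(ncol(truth))),
             TP = tp, FP = fp, FN = fn, TN = tn, support = tp + fn,
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 0/0 -> 0 with a logged warning, the conventional multi-label choice.
safe_div <- function(num, den, what) {
  bad <- den == 0
  if (any(bad & num == 0))
    warning("0/0 in ", what, " set to 0 for ", sum(bad & num == 0),
            " categor(ies)", call. = FALSE)
  out <- ifelse(bad, 0, num / den)
  as.numeric(out)
}

#' Precision, recall and F1 under a given averaging
#'
#' Computes `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)` and
#' `F1 = 2PR/(P+R)` from per-category confusion counts.  Averaging
#' schemes: `per-category` returns one row per category; `micro` pools
#' counts over categories before computing rates; `macro` is the
#' unweighted mean of per-category scores; `weighted` is the
#' support-weighted mean.  Divisions 0/0 yield 0 with a warning.
#'
#' @param counts A [confusion_counts()] data frame.
#' @param averaging One of `"per-category"`, `"micro"`, `"macro"`,
#'   `"weighted"`.
#' @return For `per-category`, a data frame; otherwise a named numeric
#'   vector `(precision, recall, f1)`.
#' @export
prf <- function(counts,
                averaging = c("per-category", "micro", "macro",
                              "weighted")) {
  averaging <- match.arg(averaging)
  p <- safe_div(counts$TP, counts$TP + counts$FP, "precision")
  r <- safe_div(counts$TP, counts$TP + counts$FN, "recall")
  f <- safe_div(2 * p * r, p + r, "f1")
  switch(averaging,
    "per-category" = data.frame(category = counts$category,
                                precision = p, recall = r, f1 = f,
                                support = counts$support,
                                row.names = NULL),
    micro = {
      mp <- safe_div(sum(counts$TP), sum(counts$TP) + sum(counts$FP),
                     "micro precision")
      mr <- safe_div(sum(counts$TP), sum(counts$TP) + sum(counts$FN),
                     "micro recall")
      c(precision = mp, recall = mr,
        f1 = safe_div(2 * mp * mr, mp + mr, "micro f1"))
    },
    macro = c(precision = mean(p), recall = mean(r), f1 = mean(f)),
    weighted = {
      w <- counts$support / sum(counts$support)
      c(precision = sum(w * p), recall = sum(w * r), f1 = sum(w * f))
    })
}

#' Per-category accuracy
#'
#' The share of test edges truly in category c that were predicted as
#' category c: `TP_c / support_c` (numerically the per-category
#' recall).  Categories with zero support are reported as `NA` and
#' excluded from summaries.
#'
#' @param counts A [confusion_counts()] data frame, or any data frame
#'   with columns `TP` and `support`.
#' @return Named numeric vector of accuracies in `[0, 1]` (`NA` where
#'   support is zero).
#' @export
per_category_accuracy <- function(counts) {
  acc <- ifelse(counts$support > 0, counts$TP / counts$support, NA_real_)
  names(acc) <- counts$category
  acc
}

#' Full multi-label evaluation report
#'
#' Bundles per-category confusion counts, precision/recall/F1 under
#' micro, macro and weighted averaging, and per-category accuracy.  The
#' headline number is the micro-F1 (`primary_f1`), the convention used
#' for cross-method comparison on PPI type prediction.
#'
#' @inheritParams confusion_counts
#' @return An object of class `metrics_report` with fields
#'   `per_category` (data frame), `micro`, `macro`, `weighted` (named
#'   vectors), and `primary_f1`.
#' @export
metrics_report <- function(pred, truth) {
  counts <- confusion_counts(pred, truth)
  percat <- suppressWarnings(prf(counts, "per-category"))
  percat$accuracy <- as.numeric(per_category_accuracy(counts))
  percat <- cbind(counts[c("category", "TP", "FP", "FN", "support")],
                  percat[c("precision", "recall", "f1", "accuracy")])
  rep <- structure(list(per_category = percat,
                        micro = suppressWarnings(prf(counts, "micro")),
                        macro = suppressWarnings(prf(counts, "macro")),
                        weighted = suppressWarnings(prf(counts,
                                                        "weighted"))),
                   class = "metrics_report")
  rep$primary_f1 <- unname(rep$micro[["f1"]])
  rep
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("<metrics_report> micro-F1 =", round(x$primary_f1, digits), "\n")
  for (avg in c("micro", "macro", "weighted"))
    cat(sprintf("  %-8s P=%.*f R=%.*f F1=%.*f\n", avg,
                digits, x[[avg]][["precision"]],
                digits, x[[avg]][["recall"]],
                digits, x[[avg]][["f1"]]))
  print(format(x$per_category, digits = digits), ...)
  invisible(x)
}

#' Write a metrics report to TSV and JSON
#'
#' @param report A [metrics_report()].
#' @param path_prefix Files `<prefix>.tsv` (per-category table) and
#'   `<prefix>.json` (full report) are written.
#' @return Invisibly, the two paths.
#' @export
write_metrics_report <- function(report, path_prefix) {
  tsv <- paste0(path_prefix, ".tsv")
  json <- paste0(path_prefix, ".json")
  utils::write.table(report$per_category, tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(micro = as.list(report$micro), macro = as.list(report$macro),
         weighted = as.list(report$weighted),
         primary_f1 = report$primary_f1,
         per_category = report$per_category),
    json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv = tsv, json = json))
}
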