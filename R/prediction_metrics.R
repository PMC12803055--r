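# Classification metrics for few-shot and probe outputs: accuracy,
# macro precision/recall, macro F1 (harmonic mean of the macro averages,
# exactly as defined - not the mean of per-class F1), one-vs-rest macro
# ROC-AUC, and top-k accuracy.

#' Construct a PredictionSet
#'
#' @param cell_ids identifiers of the scored cells.
#' @param truth ground-truth label per cell.
#' @param predicted predicted label per cell.
#' @param probabilities cells x classes matrix with named columns; rows must
#'   sum to 1 within 1e-8.
#' @return A `PredictionSet` list.
#' @export
prediction_set <- function(cell_ids, truth, predicted, probabilities) {
  cell_ids <- as.character(cell_ids)
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  probabilities <- as.matrix(probabilities)
  n <- length(cell_ids)
  assert_that(length(truth) == n && length(predicted) == n &&
                nrow(probabilities) == n, "prediction fields must align")
  assert_that(!is.null(colnames(probabilities)),
              "probability columns must be named by class")
  assert_that(all(probabilities >= -1e-12 & probabilities <= 1 + 1e-12),
              "probabilities must lie in [0,1]")
  assert_that(max(abs(rowSums(probabilities) - 1)) <= 1e-8,
              "probability rows must sum to 1")
  structure(list(cell_ids = cell_ids, truth = truth, predicted = predicted,
                 probabilities = probabilities),
            class = "PredictionSet")
}

# one-vs-rest AUC by the Mann-Whitney rank statistic; NA when a class has
# no positives or no negatives
auc_binary <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics for a prediction set
#'
#' @param pred A [prediction_set()].
#' @param top_k rank cutoff for top-k accuracy (default 3).
#' @return named list: `accuracy`, `precision_macro`, `recall_macro`,
#'   `f1_macro`, `roc_auc`, `top_k_accuracy`.
#' @details Per-class precision/recall use the 0-convention for empty
#'   denominators (with a warning); classes are the union of truth and
#'   prediction levels, so a class predicted but absent from the truth
#'   contributes recall 0. Macro F1 is the harmonic mean of macro precision
#'   and macro recall. ROC-AUC is one-vs-rest with an unweighted macro
#'   average over classes present in the truth. Top-k ranks ties by class
#'   (column) order.
#' @export
classification_report <- function(pred, top_k = 3L) {
  stopifnot(inherits(pred, "PredictionSet"))
  truth <- pred$truth; predicted <- pred$predicted
  assert_that(length(unique(truth)) >= 2, "need >= 2 classes in the truth")
  classes <- sort(union(unique(truth), unique(predicted)))
  acc <- mean(predicted == truth)
  prec <- rec <- numeric(length(classes))
  warned <- FALSE
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    tp <- sum(predicted == cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    if (tp + fp == 0 || tp + fn == 0) warned <- TRUE
    prec[ci] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[ci] <- if (tp + fn == 0) 0 else tp / (tp + fn)
  }
  if (warned) warning("class with empty precision/recall denominator scored 0")
  pm <- mean(prec); rm_ <- mean(rec)
  f1 <- if (pm + rm_ == 0) 0 else 2 * pm * rm_ / (pm + rm_)

  # ROC-AUC: macro one-vs-rest over classes present in the truth
  probs <- pred$probabilities
  auc_cls <- vapply(intersect(classes, colnames(probs)), function(cl) {
    if (!cl %in% truth) return(NA_real_)
    auc_binary(probs[, cl], truth == cl)
  }, numeric(1))
  roc_auc <- mean(auc_cls, na.rm = TRUE)

  # top-k: ties broken by class (column) order via order()'s stable index
  k <- min(top_k, ncol(probs))
  topk_hit <- vapply(seq_along(truth), function(i) {
    o <- order(-probs[i, ], seq_len(ncol(probs)))[seq_len(k)]
    truth[i] %in% colnames(probs)[o]
  }, logical(1))

  list(accuracy = acc, precision_macro = pm, recall_macro = rm_,
       f1_macro = f1, roc_auc = roc_auc, top_k_accuracy = mean(topk_hit))
}
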