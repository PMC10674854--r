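#' Exact-match accuracy
#'
#' Fraction of predictions equal to the ground-truth severity score.
#'
#' @param pred,truth integer score vectors of equal length.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy_t1 <- function(pred, truth) {
  check_paired(pred, truth)
  mean(pred == truth)
}

#' Acceptable (within-one) accuracy
#'
#' Fraction of predictions within one point of the ground truth. A deviation
#' of one severity point falls inside typical inter-rater disagreement, so
#' this is the clinically "acceptable" accuracy; it is never smaller than
#' [accuracy_t1()].
#'
#' @param pred,truth integer score vectors of equal length.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy_t2 <- function(pred, truth) {
  check_paired(pred, truth)
  mean(abs(pred - truth) <= 1)
}

check_paired <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("pred and truth differ in length", call. = FALSE)
  }
  if (length(pred) < 1L) stop("empty score vectors", call. = FALSE)
  invisible(TRUE)
}

#' 5x5 severity confusion matrix
#'
#' Counts of (truth, prediction) pairs; rows are ground-truth scores 0-4,
#' columns predictions. Its trace over the total is [accuracy_t1()] and the
#' tri-diagonal band total is [accuracy_t2()].
#'
#' @param pred,truth integer score vectors with values in 0-4.
#' @return 5x5 integer matrix with dimnames `truth` x `pred`.
#' @export
confusion_matrix <- function(pred, truth) {
  check_paired(pred, truth)
  if (any(!(pred %in% 0:4)) || any(!(truth %in% 0:4))) {
    stop("scores must lie in 0-4", call. = FALSE)
  }
  m <- table(factor(truth, levels = 0:4), factor(pred, levels = 0:4))
  m <- matrix(as.integer(m), 5, 5,
              dimnames = list(truth = 0:4, pred = 0:4))
  m
}

#' Per-class and macro precision, recall and F-beta
#'
#' One-vs-rest precision `TP / (TP + FP)`, recall `TP / (TP + FN)` and
#' `F_beta = (1 + beta^2) P R / (beta^2 P + R)` for each severity class,
#' plus unweighted (macro) means over the classes present in the ground
#' truth. A class with no predicted positives has precision 0 by convention
#' and is flagged in the `zero_division` attribute; the same convention
#' applies to recall for classes absent from the truth and to F when both
#' P and R are 0.
#'
#' @param pred,truth integer score vectors with values in 0-4.
#' @param beta F-score weight (1 = balanced; 2 weights recall higher).
#' @return List with `per_class` (data frame: class, n, precision, recall,
#'   f) and `macro` (named vector over classes present in truth), plus the
#'   `zero_division` attribute on `per_class`.
#' @export
precision_recall_f <- function(pred, truth, beta = 1) {
  check_paired(pred, truth)
  stopifnot(beta > 0)
  cm <- confusion_matrix(pred, truth)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f <- ifelse(precision + recall > 0,
              (1 + beta^2) * precision * recall /
                (beta^2 * precision + recall), 0)
  per_class <- data.frame(class = 0:4, n = rowSums(cm),
                          precision = unname(precision),
                          recall = unname(recall), f = unname(f))
  attr(per_class, "zero_division") <- (0:4)[tp + fp == 0]
  present <- rowSums(cm) > 0
  macro <- c(precision = mean(precision[present]),
             recall = mean(recall[present]),
             f = mean(f[present]))
  list(per_class = per_class, macro = macro, beta = beta)
}

#' Inter-annotator agreement summary
#'
#' Percentages of items on which two raters agree completely (identical
#' scores), acceptably (scores differing by at most 1) and not at all
#' (difference greater than 1). Complete never exceeds acceptable, and
#' acceptable + none = 100.
#'
#' @param rater1,rater2 integer score vectors of equal length.
#' @return Named numeric vector `c(complete, acceptable, none)` in percent.
#' @export
annotator_agreement <- function(rater1, rater2) {
  check_paired(rater1, rater2)
  d <- abs(rater1 - rater2)
  c(complete = 100 * mean(d == 0),
    acceptable = 100 * mean(d <= 1),
    none = 100 * mean(d > 1))
}

#' Full evaluation report
#'
#' Bundles both accuracies, the confusion matrix, and per-class plus macro
#' precision/recall/F into one object, the standard summary of a scored
#' test set.
#'
#' @param pred,truth integer score vectors with values in 0-4.
#' @param beta F-score weight (default 1).
#' @return An object of class `eval_report`.
#' @export
eval_report <- function(pred, truth, beta = 1) {
  prf <- precision_recall_f(pred, truth, beta = beta)
  structure(list(accuracy_t1 = accuracy_t1(pred, truth),
                 accuracy_t2 = accuracy_t2(pred, truth),
                 confusion = confusion_matrix(pred, truth),
                 per_class = prf$per_class, macro = prf$macro,
                 beta = beta, n = length(pred)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d\n", x$n))
  cat(sprintf("  Accuracy(t1) exact:      %.3f\n", x$accuracy_t1))
  cat(sprintf("  Accuracy(t2) within one: %.3f\n", x$accuracy_t2))
  cat(sprintf("  Macro precision/recall/F%g: %.3f / %.3f / %.3f\n",
              x$beta, x$macro["precision"], x$macro["recall"], x$macro["f"]))
  cat("  Confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}
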