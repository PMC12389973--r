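# Classification metrics. Positive class = depressed (label 0).

#' Evaluation report from predictions and labels
#'
#' Computes the confusion matrix with the depressed class (label 0) as
#' positive, and ACC, PRE, REC and F1 as percentages (2 decimals).
#' Precision (and F1) are reported as 0 with a flag when undefined
#' (no positive predictions).
#'
#' @param predictions integer vector of predicted labels (0/1).
#' @param labels integer vector of true labels (0/1).
#' @return an `eval_report` list: `TP`, `TN`, `FP`, `FN`, `ACC`, `PRE`,
#'   `REC`, `F1` (percent), `confusion` (2 x 2 matrix), and
#'   `undefined` (character vector of metrics hit by 0/0).
#' @export
evaluate_predictions <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels))
  pos <- 0L
  tp <- sum(predictions == pos & labels == pos)
  tn <- sum(predictions != pos & labels != pos)
  fp <- sum(predictions == pos & labels != pos)
  fn <- sum(predictions != pos & labels == pos)
  undefined <- character()
  acc <- (tp + tn) / (tp + tn + fp + fn)
  if (tp + fp == 0) {
    pre <- 0
    undefined <- c(undefined, "PRE")
  } else pre <- tp / (tp + fp)
  if (tp + fn == 0) {
    rec <- 0
    undefined <- c(undefined, "REC")
  } else rec <- tp / (tp + fn)
  f1 <- if (pre + rec == 0) {
    undefined <- c(undefined, "F1")
    0
  } else 2 * pre * rec / (pre + rec)
  conf <- matrix(c(tp, fn, fp, tn), 2, 2,
                 dimnames = list(true = c("DP", "HC"),
                                 predicted = c("DP", "HC")))
  structure(
    list(TP = tp, TN = tn, FP = fp, FN = fn,
         ACC = round(100 * acc, 2), PRE = round(100 * pre, 2),
         REC = round(100 * rec, 2), F1 = round(100 * f1, 2),
         confusion = conf, undefined = undefined),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("ACC %.2f%%  PRE %.2f%%  REC %.2f%%  F1 %.2f%%\n",
              x$ACC, x$PRE, x$REC, x$F1))
  print(x$confusion)
  invisible(x)
}
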