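#' Confusion counts at a threshold
#'
#' Predicts class 1 when `score >= threshold` (the same convention the
#' fitted models use) and cross-tabulates against the 0/1 labels.
#'
#' @param labels 0/1 vector of true classes.
#' @param scores numeric vector of scores or probabilities.
#' @param threshold classification threshold (default 0.5).
#' @return list of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(labels, scores, threshold = 0.5) {
  if (!length(labels)) stop("empty input", call. = FALSE)
  if (length(labels) != length(scores))
    stop("labels and scores differ in length", call. = FALSE)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  pred <- as.numeric(scores >= threshold)
  structure(list(tp = sum(pred == 1 & labels == 1),
                 fp = sum(pred == 1 & labels == 0),
                 tn = sum(pred == 0 & labels == 0),
                 fn = sum(pred == 0 & labels == 1)),
            class = "confusion_counts")
}

#' Confusion-matrix summary metrics
#'
#' TPR (recall), TNR, FPR, FNR, precision, F-score, and accuracy from a
#' [confusion_counts()] object.  A zero denominator yields `NA` (an
#' undefined marker), never 0.
#'
#' @param counts a `confusion_counts` object.
#' @return named list with `tpr`, `tnr`, `fpr`, `fnr`, `precision`,
#'   `f_score`, `accuracy` (and `auc = NA`, filled by [metrics_report()]).
#' @export
summarize_confusion <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  tpr <- rat(counts$tp, counts$tp + counts$fn)
  tnr <- rat(counts$tn, counts$tn + counts$fp)
  pre <- rat(counts$tp, counts$tp + counts$fp)
  fs <- if (is.na(pre) || is.na(tpr) || pre + tpr == 0) NA_real_
        else 2 * pre * tpr / (pre + tpr)
  n <- counts$tp + counts$fp + counts$tn + counts$fn
  list(tpr = tpr, tnr = tnr, fpr = if (is.na(tnr)) NA_real_ else 1 - tnr,
       fnr = if (is.na(tpr)) NA_real_ else 1 - tpr,
       precision = pre, f_score = fs, accuracy = (counts$tp + counts$tn) / n,
       auc = NA_real_)
}

#' Rank-based AUC
#'
#' Mann-Whitney formulation: the proportion of positive-negative pairs in
#' which the positive scores higher, ties counted half.  Midranks make
#' this identical to the trapezoidal ROC area.
#'
#' @inheritParams confusion_counts
#' @return AUC in `[0, 1]`, or `NA` when only one class is present.
#' @export
taba_auc <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop("labels and scores differ in length", call. = FALSE)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-row classification metrics report
#'
#' The eight headline metrics (TPR, TNR, FPR, FNR, PRE, FS, Accuracy,
#' AUC) in that column order, as a one-row data frame.
#'
#' @inheritParams confusion_counts
#' @param model_name optional row label.
#' @export
metrics_report <- function(labels, scores, threshold = 0.5,
                           model_name = "model") {
  s <- summarize_confusion(confusion_counts(labels, scores, threshold))
  s$auc <- taba_auc(labels, scores)
  data.frame(Model = model_name, TPR = s$tpr, TNR = s$tnr, FPR = s$fpr,
             FNR = s$fnr, PRE = s$precision, FS = s$f_score,
             Accuracy = s$accuracy, AUC = s$auc,
             row.names = NULL, stringsAsFactors = FALSE)
}
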