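#' Rank-based ROC AUC
#'
#' Computed from midranks, so ties are credited one half; equals the
#' Mann-Whitney U statistic divided by `n_pos * n_neg` exactly.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (logical or 0/1); both classes required.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("missing values in scores or labels", call. = FALSE)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Build a confusion matrix at a decision threshold
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param labels Binary truth.
#' @param threshold Decision threshold (default 0.5; `score >= threshold`
#'   predicts the positive class).
#' @return A `confusion_matrix` list with integer `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at <- function(scores, labels, threshold = 0.5) {
  labels <- as.logical(labels)
  pred <- scores >= threshold
  structure(list(tp = sum(pred & labels), fp = sum(pred & !labels),
                 tn = sum(!pred & !labels), fn = sum(!pred & labels)),
            class = "confusion_matrix")
}

#' Confusion-derived performance metrics
#'
#' Closed forms: sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`,
#' precision `tp/(tp+fp)`, accuracy `(tp+tn)/n`, F1 `2tp/(2tp+fp+fn)`.
#' A metric whose denominator is zero is reported `NA` (absent). Values are
#' stored at full precision; the print method rounds to 3 decimals.
#'
#' @param cm A `confusion_matrix` (see [confusion_at()]) or a list with
#'   fields `tp`, `fp`, `tn`, `fn`.
#' @return A `classifier_metrics` list: `sensitivity`, `specificity`,
#'   `precision`, `accuracy`, `f1`, plus the confusion counts.
#' @export
metrics_from_confusion <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || anyNA(counts)) stop("confusion counts must be non-negative", call. = FALSE)
  n <- sum(counts)
  if (n == 0L) stop("all-zero confusion matrix", call. = FALSE)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  structure(list(
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    precision = safe_div(tp, tp + fp),
    accuracy = (tp + tn) / n,
    f1 = safe_div(2 * tp, 2 * tp + fp + fn),
    tp = tp, fp = fp, tn = tn, fn = fn
  ), class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf("Confusion: tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn, x$fn))
  for (m in c("sensitivity", "specificity", "precision", "accuracy", "f1")) {
    cat(sprintf("%-12s %s\n", m, ifelse(is.na(x[[m]]), "NA", sprintf("%.3f", x[[m]]))))
  }
  invisible(x)
}

#' Write an evaluation report as a machine-parsable key-value file
#'
#' One `key<TAB>value` pair per line, deterministic order, no timestamps.
#'
#' @param report Named list of scalars (numeric, character or logical).
#' @param path Output path.
#' @export
write_metrics_report <- function(report, path) {
  flat <- unlist(report)
  lines <- sprintf("%s\t%s", names(flat),
                   vapply(flat, function(v) {
                     if (is.numeric(v)) sprintf("%.6g", v) else as.character(v)
                   }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
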