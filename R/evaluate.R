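#' Cross-validated pipeline evaluation
#'
#' Fits the pipeline's head on k-1 folds and scores the held-out fold, for
#' every fold of the plan. Folds whose training rows contain a single class
#' are skipped with a warning; held-out AUC is `NA` for folds whose test
#' rows contain a single class.
#'
#' @param pipeline A [pipeline_spec()].
#' @param dataset A `cdp_dataset`.
#' @param plan A [make_balanced_folds()] plan for the dataset's records.
#' @param X Optional precomputed feature matrix from [build_features()]
#'   (reuse it to share one kernel bank across evaluations).
#' @return A `cv_result`: `per_fold_auc`, `mean_auc`, `sd_auc`,
#'   out-of-fold `scores` (NA for skipped folds), `labels`, and the plan.
#' @export
cross_validate <- function(pipeline, dataset, plan, X = NULL) {
  stopifnot(inherits(plan, "fold_plan"))
  if (is.null(X)) X <- build_features(pipeline, dataset)
  y <- dataset$records$expressed
  scores <- rep(NA_real_, length(y))
  per_fold <- rep(NA_real_, plan$k)
  with_seed(pipeline$seed, {
    for (f in seq_len(plan$k)) {
      test <- which(plan$assignment == f)
      train <- which(plan$assignment != f)
      if (length(test) == 0L) next
      if (length(unique(y[train])) < 2L) {
        warning(sprintf("fold %d skipped: single-class training set", f), call. = FALSE)
        next
      }
      s <- fit_and_score(pipeline, X, y, train, test)
      scores[test] <- s
      if (length(unique(y[test])) == 2L) per_fold[f] <- roc_auc(s, y[test])
    }
  })
  structure(list(per_fold_auc = per_fold,
                 mean_auc = mean(per_fold, na.rm = TRUE),
                 sd_auc = sd(per_fold, na.rm = TRUE),
                 scores = scores, labels = y, plan = plan,
                 pipeline = pipeline),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV: mean AUC %.3f (SD %.3f) over %d scored folds\n",
              x$plan$k, x$mean_auc, x$sd_auc, sum(!is.na(x$per_fold_auc))))
  invisible(x)
}

#' Leave-one-out cross-validation with aggregated confidences
#'
#' Trains one model per sample (on all other samples), collects each
#' sample's held-out confidence, and computes a single ROC AUC over the
#' aggregated confidences plus a confusion matrix at the 0.5 decision
#' threshold with the full metric set.
#'
#' @param pipeline A [pipeline_spec()].
#' @param dataset A `cdp_dataset`.
#' @param X Optional precomputed features (see [cross_validate()]).
#' @return An `eval_report`: `auc`, `confusion`, `metrics`
#'   ([metrics_from_confusion()]), per-sample `scores`, `labels`, `n`.
#' @export
loocv <- function(pipeline, dataset, X = NULL) {
  if (is.null(X)) X <- build_features(pipeline, dataset)
  y <- dataset$records$expressed
  n <- length(y)
  if (n < 10L) warning("fewer than 10 records; LOOCV estimates will be unstable", call. = FALSE)
  scores <- rep(NA_real_, n)
  with_seed(pipeline$seed, {
    for (i in seq_len(n)) {
      train <- setdiff(seq_len(n), i)
      scores[i] <- fit_and_score(pipeline, X, y, train, i)
    }
  })
  cm <- confusion_at(scores, y, threshold = 0.5)
  structure(list(auc = roc_auc(scores, y), confusion = cm,
                 metrics = metrics_from_confusion(cm),
                 scores = scores, labels = y, n = n, scheme = "loocv",
                 pipeline = pipeline),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("LOOCV over %d records: AUC %.3f\n", x$n, x$auc))
  print(x$metrics)
  invisible(x)
}
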