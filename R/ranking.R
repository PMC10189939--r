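#' Permutation-based model ranking with critical-difference grouping
#'
#' Each permutation draws one stratified train/validation split (90-10 by
#' default) shared by all models; every model is trained on the training
#' part and its validation AUC recorded. Models are ranked per permutation
#' (rank 1 = highest AUC, ties averaged) and mean ranks computed. Grouping
#' uses the standard two-step procedure for comparing classifiers over
#' repeated evaluations: a Friedman omnibus test, then the Nemenyi critical
#' difference `CD = q_alpha * sqrt(k (k + 1) / (6 N))` (with `q_alpha` the
#' Studentized-range quantile divided by sqrt(2)); two models share a group
#' when the omnibus is non-significant or their mean ranks differ by less
#' than CD. The result carries everything needed to draw a
#' critical-difference diagram.
#'
#' @param pipelines Named list of [pipeline_spec()]s (>= 2).
#' @param dataset A `cdp_dataset`.
#' @param n_permutations Number of random splits (default 50).
#' @param train_fraction Training fraction per split (default 0.9).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed for the splits (and any stochastic heads).
#' @return A `ranking_result`: `mean_rank`, `auc` (permutations x models),
#'   `ranks`, `same_group` (logical matrix), `cd`, `friedman_p`,
#'   `n_permutations`, `train_fraction`, `alpha`, and `table` (a
#'   plotting-ready data.frame of model, mean rank and group membership).
#' @export
rank_models <- function(pipelines, dataset, n_permutations = 50L,
                        train_fraction = 0.9, alpha = 0.05, seed = 1L) {
  stopifnot(is.list(pipelines), length(pipelines) >= 2L, !is.null(names(pipelines)))
  if (n_permutations < 2L) stop("need at least 2 permutations", call. = FALSE)
  k <- length(pipelines)
  features <- lapply(pipelines, build_features, dataset = dataset)
  y <- dataset$records$expressed
  auc <- matrix(NA_real_, n_permutations, k, dimnames = list(NULL, names(pipelines)))
  with_seed(seed, {
    for (p in seq_len(n_permutations)) {
      split <- stratified_split(dataset$records, train_fraction)
      for (m in seq_len(k)) {
        s <- fit_and_score(pipelines[[m]], features[[m]], y, split$train, split$test)
        auc[p, m] <- roc_auc(s, y[split$test])
      }
    }
  })
  ranks <- t(apply(-auc, 1, rank)) # rank 1 = best AUC, ties averaged
  mean_rank <- colMeans(ranks)

  fr <- suppressWarnings(friedman.test(auc))
  friedman_p <- fr$p.value
  if (!is.finite(friedman_p)) friedman_p <- 1 # degenerate (e.g. identical models)

  q_alpha <- qtukey(1 - alpha, k, Inf) / sqrt(2)
  cd <- q_alpha * sqrt(k * (k + 1) / (6 * n_permutations))
  diff_mat <- abs(outer(mean_rank, mean_rank, "-"))
  same_group <- if (friedman_p >= alpha) {
    matrix(TRUE, k, k, dimnames = dimnames(diff_mat))
  } else {
    diff_mat < cd
  }

  structure(list(mean_rank = mean_rank, auc = auc, ranks = ranks,
                 same_group = same_group, cd = cd, friedman_p = friedman_p,
                 n_permutations = as.integer(n_permutations),
                 train_fraction = train_fraction, alpha = alpha,
                 table = data.frame(model = names(pipelines),
                                    mean_rank = unname(mean_rank),
                                    mean_auc = unname(colMeans(auc)))),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("Model ranking over %d permutations (CD = %.3f at alpha = %g, Friedman p = %.3g)\n",
              x$n_permutations, x$cd, x$alpha, x$friedman_p))
  print(x$table[order(x$table$mean_rank), ], row.names = FALSE)
  invisible(x)
}

#' Paired permutation test on cross-validated AUC
#'
#' Both pipelines are scored on the same balanced fold plan; the observed
#' statistic is the difference of their aggregated out-of-fold AUCs. The
#' null is built by randomly exchanging the two models' scores -- per
#' sample by default (paired exchangeability), or per fold -- and the
#' two-tailed Monte-Carlo p-value uses +1 smoothing, `p = (b + 1) / (m +
#' 1)`, so it is never exactly zero.
#'
#' @param pipeline_a,pipeline_b [pipeline_spec()]s to compare.
#' @param dataset A `cdp_dataset`.
#' @param n_iterations Permutations (default 10000).
#' @param k Folds for the shared CV (default 10).
#' @param unit Exchange `"sample"` score pairs (default) or whole
#'   `"fold"`s.
#' @param seed Integer seed (fold plan and permutations).
#' @return List with `p_value`, `observed` (AUC_a - AUC_b), `auc_a`,
#'   `auc_b`, `n_iterations`, `unit`.
#' @export
paired_permutation_test_auc <- function(pipeline_a, pipeline_b, dataset,
                                        n_iterations = 10000L, k = 10L,
                                        unit = c("sample", "fold"), seed = 1L) {
  unit <- match.arg(unit)
  plan <- make_balanced_folds(dataset$records, k = k, seed = seed)
  y <- dataset$records$expressed
  cva <- cross_validate(pipeline_a, dataset, plan)
  cvb <- cross_validate(pipeline_b, dataset, plan)
  keep <- !is.na(cva$scores) & !is.na(cvb$scores)
  sa <- cva$scores[keep]; sb <- cvb$scores[keep]
  yy <- y[keep]; fold <- plan$assignment[keep]
  auc_a <- roc_auc(sa, yy); auc_b <- roc_auc(sb, yy)
  obs <- auc_a - auc_b
  null_stats <- with_seed(seed + 1L, vapply(seq_len(n_iterations), function(i) {
    swap <- if (unit == "sample") {
      runif(length(sa)) < 0.5
    } else {
      (runif(max(fold)) < 0.5)[fold]
    }
    s1 <- ifelse(swap, sb, sa)
    s2 <- ifelse(swap, sa, sb)
    roc_auc(s1, yy) - roc_auc(s2, yy)
  }, numeric(1)))
  b <- sum(abs(null_stats) >= abs(obs) - 1e-12)
  list(p_value = (b + 1) / (n_iterations + 1), observed = obs,
       auc_a = auc_a, auc_b = auc_b,
       n_iterations = as.integer(n_iterations), unit = unit)
}
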