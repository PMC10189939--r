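#' Shapley attribution for forest models
#'
#' Computes per-sample, per-feature signed contributions to the predicted
#' probability of expression using the exact tree-path (TreeSHAP-style)
#' algorithm, satisfying local accuracy: `base_value + sum(contributions)`
#' equals the forest probability for each sample. Attribution is restricted
#' to forests trained on position-resolved (flattened) features: a kernel
#' transform breaks the link between features and residue positions, so
#' transformed models are rejected.
#'
#' A Monte-Carlo permutation-sampling estimator (`method = "sampling"`) is
#' available as a generic fallback; it marginalizes features against a
#' background sample (interventional conditioning), which agrees with the
#' exact algorithm on trees whose split features are independent, and its
#' seed and draw count are recorded in the result.
#'
#' @param model A `cdp_model` with a random-forest head.
#' @param X Feature matrix to attribute (same provenance as training).
#' @param method `"tree"` (exact, default) or `"sampling"`.
#' @param n_draws Monte-Carlo draws per sample for `"sampling"` (>= 2000
#'   recommended).
#' @param seed Seed for the sampling estimator.
#' @return An `attribution_set`: `contributions` (n x p matrix),
#'   `base_value`, `provenance`, `predicted` (forest probabilities) and the
#'   estimator settings.
#' @export
attribute_forest <- function(model, X, method = c("tree", "sampling"),
                             n_draws = 2000L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(model, "cdp_model"))
  if (model$head != "random_forest") {
    stop("attribution is only defined for random-forest models", call. = FALSE)
  }
  prov <- model$provenance
  if (!is.null(prov) && "kernel" %in% names(prov)) {
    stop("kernel-transformed features carry no positional provenance; attribution refused",
         call. = FALSE)
  }
  check_feature_matrix(X)
  xprov <- attr(X, "provenance")
  if (!is.null(prov) && !is.null(xprov) &&
      !isTRUE(all.equal(prov, xprov, check.attributes = FALSE))) {
    stop("feature provenance does not match the training features", call. = FALSE)
  }
  predicted <- predict_scores(model, X)

  if (method == "tree") {
    forest <- extract_forest(model$fit)
    res <- treeshap_cpp(X, model$X_train, forest)
    contributions <- res$phi
    base <- res$base
  } else {
    bg <- model$X_train
    contributions <- mc_shapley(function(M) {
      attr(M, "provenance") <- xprov
      predict_scores(model, M)
    }, X, bg, n_draws = n_draws, seed = seed)
    base <- mean(predict_scores(model, bg))
  }
  structure(list(contributions = contributions, base_value = base,
                 provenance = prov, predicted = predicted,
                 method = method,
                 n_draws = if (method == "sampling") as.integer(n_draws) else NA_integer_,
                 seed = if (method == "sampling") as.integer(seed) else NA_integer_),
            class = "attribution_set")
}

# Flatten a fitted ranger probability forest into plain arrays for the
# compiled tree-path algorithm. Leaf value = terminal fraction of the
# positive ("yes") class.
extract_forest <- function(fit) {
  lapply(seq_len(fit$num.trees), function(t) {
    ti <- ranger::treeInfo(fit, t)
    predcol <- grep("^pred", names(ti), value = TRUE)
    pos <- predcol[endsWith(predcol, "yes")]
    list(left = ifelse(is.na(ti$leftChild), -1L, as.integer(ti$leftChild)),
         right = ifelse(is.na(ti$rightChild), -1L, as.integer(ti$rightChild)),
         feature = ifelse(ti$terminal, -1L, as.integer(ti$splitvarID)),
         threshold = ifelse(is.na(ti$splitval), 0, as.numeric(ti$splitval)),
         value = ifelse(is.na(ti[[pos]]), 0, as.numeric(ti[[pos]])))
  })
}

# Castro-style permutation sampling of Shapley values against a background
# sample. O(n_draws * p) model calls per attributed row; intended for small
# feature counts.
mc_shapley <- function(predict_fun, X, background, n_draws, seed) {
  p <- ncol(X)
  n <- nrow(X)
  phi <- matrix(0, n, p)
  with_seed(seed, {
    for (s in seq_len(n)) {
      x <- X[s, ]
      acc <- numeric(p)
      for (d in seq_len(n_draws)) {
        perm <- sample.int(p)
        z <- background[sample.int(nrow(background), 1L), ]
        cur <- z
        prev <- predict_fun(matrix(cur, 1L))
        for (j in perm) {
          cur[j] <- x[j]
          val <- predict_fun(matrix(cur, 1L))
          acc[j] <- acc[j] + (val - prev)
          prev <- val
        }
      }
      phi[s, ] <- acc / n_draws
    }
  })
  phi
}

#' Positional importance profile
#'
#' Sums absolute contributions over samples and channels at each residue
#' position, then normalizes for the padding-induced undercounting of
#' C-terminal positions: by default position `p` is divided by the number
#' of peptides long enough to occupy it (`length >= p`). The literal
#' per-exact-length normalization (divide by the number of peptides of
#' exactly that length) is available as `mode = "exact_length"`. Positions
#' with no eligible peptide are reported `NA`.
#'
#' @param attr An `attribution_set` whose provenance carries positions.
#' @param lengths Integer vector of true (unpadded) lengths per attributed
#'   sample.
#' @param mode `"occupied"` (default) or `"exact_length"`.
#' @return data.frame with `position`, `raw`, `n_eligible`, `normalized`.
#' @export
importance_by_position <- function(attr, lengths, mode = c("occupied", "exact_length")) {
  mode <- match.arg(mode)
  stopifnot(inherits(attr, "attribution_set"))
  prov <- attr$provenance
  if (is.null(prov) || all(is.na(prov$position))) {
    stop("attribution provenance carries no positions", call. = FALSE)
  }
  stopifnot(length(lengths) == nrow(attr$contributions))
  positions <- sort(unique(prov$position))
  abs_c <- abs(attr$contributions)
  raw <- vapply(positions, function(p) sum(abs_c[, prov$position == p, drop = FALSE]),
                numeric(1))
  n_eligible <- if (mode == "occupied") {
    vapply(positions, function(p) sum(lengths >= p), numeric(1))
  } else {
    vapply(positions, function(p) sum(lengths == p), numeric(1))
  }
  data.frame(position = positions, raw = raw, n_eligible = n_eligible,
             normalized = ifelse(n_eligible > 0, raw / n_eligible, NA_real_))
}

#' Per-representation-block importance
#'
#' Sums absolute contributions over samples, positions and channels within
#' each representation block. Together with [importance_by_position()] it
#' partitions the same total absolute attribution.
#'
#' @param attr An `attribution_set` whose provenance carries block labels.
#' @return Named numeric vector, one entry per block present.
#' @export
importance_by_block <- function(attr) {
  stopifnot(inherits(attr, "attribution_set"))
  prov <- attr$provenance
  if (is.null(prov) || is.null(prov$block)) {
    stop("attribution provenance carries no block labels", call. = FALSE)
  }
  totals <- colSums(abs(attr$contributions))
  out <- tapply(totals, prov$block, sum)
  canonical <- c("single", "pair_reduced", "msa", "structure")
  if (all(names(out) %in% canonical)) out <- out[intersect(canonical, names(out))]
  unlist(as.list(out))
}

#' Compare mean pLDDT between correctly and incorrectly predicted peptides
#'
#' Splits records into correct (TP and TN) versus incorrect (FP and FN)
#' predictions at the 0.5 threshold and compares the groups' mean pLDDT
#' with the Mann-Whitney test. If either group is empty, the test is
#' skipped and the p-value reported `NA`.
#'
#' @param mean_plddt Numeric per-record mean pLDDT.
#' @param predictions Scores in \[0, 1\] or binary predictions.
#' @param labels Binary truth.
#' @return List with group sizes, medians, interquartile ranges, `U` and
#'   `p_value`.
#' @export
compare_plddt_by_outcome <- function(mean_plddt, predictions, labels) {
  labels <- as.logical(labels)
  pred <- predictions >= 0.5
  correct <- pred == labels
  a <- mean_plddt[correct]
  b <- mean_plddt[!correct]
  iqr <- function(v) if (length(v)) unname(diff(quantile(v, c(0.25, 0.75)))) else NA_real_
  out <- list(n_correct = length(a), n_incorrect = length(b),
              median_correct = if (length(a)) median(a) else NA_real_,
              median_incorrect = if (length(b)) median(b) else NA_real_,
              iqr_correct = iqr(a), iqr_incorrect = iqr(b),
              U = NA_real_, p_value = NA_real_, skipped = FALSE)
  if (length(a) == 0L || length(b) == 0L) {
    out$skipped <- TRUE
    cdp_log("one outcome group is empty; Mann-Whitney comparison skipped")
    return(out)
  }
  mw <- mann_whitney_u(a, b)
  out$U <- mw$U
  out$p_value <- mw$p_value
  out
}
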