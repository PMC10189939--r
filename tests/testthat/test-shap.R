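# Brute-force Shapley oracle over the path-dependent value function of a
# single tree: v(S) follows x on split features in S and cover-weights the
# children otherwise. Exact by subset enumeration; small trees only.
cover_of <- function(tr, Xtr) {
  cov <- numeric(length(tr$left))
  for (s in seq_len(nrow(Xtr))) {
    nd <- 1L
    repeat {
      cov[nd] <- cov[nd] + 1
      if (tr$feature[nd] < 0) break
      nd <- if (Xtr[s, tr$feature[nd] + 1] <= tr$threshold[nd]) tr$left[nd] + 1L
            else tr$right[nd] + 1L
    }
  }
  cov
}

tree_value <- function(tr, cov, x, S, nd = 1L) {
  if (tr$feature[nd] < 0) return(tr$value[nd])
  f <- tr$feature[nd] + 1L
  l <- tr$left[nd] + 1L
  r <- tr$right[nd] + 1L
  if (f %in% S) {
    if (x[f] <= tr$threshold[nd]) tree_value(tr, cov, x, S, l)
    else tree_value(tr, cov, x, S, r)
  } else {
    (cov[l] * tree_value(tr, cov, x, S, l) + cov[r] * tree_value(tr, cov, x, S, r)) / cov[nd]
  }
}

brute_shapley <- function(tr, cov, x, p) {
  phi <- numeric(p)
  for (i in seq_len(p)) {
    others <- setdiff(seq_len(p), i)
    for (k in 0:length(others)) {
      subsets <- if (k == 0) list(integer(0)) else asplit(combn(others, k), 2)
      w <- factorial(k) * factorial(p - k - 1) / factorial(p)
      for (S in subsets) {
        phi[i] <- phi[i] + w * (tree_value(tr, cov, x, c(S, i)) - tree_value(tr, cov, x, S))
      }
    }
  }
  phi
}

fit_flat_forest <- function(n = 70, p = 6, n_trees = 10, seed = 3, informative = c(2, 5)) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- rowSums(X[, informative, drop = FALSE]) + rnorm(n) * 0.6 > 0
  attr(X, "provenance") <- data.frame(block = "single",
                                      position = rep(seq_len(p / 2), each = 2),
                                      channel = rep(1:2, p / 2))
  m <- fit_classifier(classifier_spec("random_forest", n_trees = n_trees, seed = seed), X, y)
  list(X = X, y = y, model = m)
}

test_that("tree-path attributions equal brute-force Shapley enumeration", {
  f <- fit_flat_forest()
  at <- attribute_forest(f$model, f$X)
  ex <- cdpexpress:::extract_forest(f$model$fit)
  for (s in 1:4) {
    total <- numeric(ncol(f$X))
    for (tr in ex) {
      cov <- cover_of(tr, f$model$X_train)
      total <- total + brute_shapley(tr, cov, f$X[s, ], ncol(f$X))
    }
    expect_equal(at$contributions[s, ], total / length(ex), tolerance = 1e-10)
  }
})

test_that("attributions satisfy local accuracy on every sample", {
  f <- fit_flat_forest(n = 120, n_trees = 40, seed = 11)
  at <- attribute_forest(f$model, f$X)
  recon <- at$base_value + rowSums(at$contributions)
  expect_equal(recon, at$predicted, tolerance = 1e-6)
})

test_that("a single stump concentrates its attribution on the split feature", {
  # force one split: two well-separated clusters on feature 1
  n <- 40
  X <- cbind(rep(c(-2, 2), each = n / 2), 0.01 * rnorm(n))
  y <- rep(c(FALSE, TRUE), each = n / 2)
  m <- fit_classifier(classifier_spec("random_forest", n_trees = 1, seed = 2), X, y)
  ti <- ranger::treeInfo(m$fit, 1)
  skip_if(sum(!ti$terminal) != 1, "forest did not produce a single stump")
  at <- attribute_forest(m, X)
  expect_equal(at$contributions[, 2], rep(0, n))
  expect_equal(at$contributions[, 1], at$predicted - at$base_value, tolerance = 1e-12)
})

test_that("attribution refuses non-forest models and kernel-transformed features", {
  toy_y <- rep(c(TRUE, FALSE), 15)
  X <- matrix(rnorm(60), 30, 2)
  lr <- fit_classifier(classifier_spec("l2_logreg", seed = 1), X, toy_y)
  expect_error(attribute_forest(lr, X), "random-forest")

  Xr <- matrix(rnorm(60), 30, 2)
  attr(Xr, "provenance") <- data.frame(kernel = rep(1L, 2), stat = c("ppv", "max"))
  rf <- fit_classifier(classifier_spec("random_forest", n_trees = 10, seed = 1), Xr, toy_y)
  expect_error(attribute_forest(rf, Xr), "positional provenance")
})

test_that("Monte-Carlo sampling attribution agrees with the exact method on a stump", {
  n <- 40
  X <- cbind(rep(c(-2, 2), each = n / 2), 0.01 * rnorm(n))
  y <- rep(c(FALSE, TRUE), each = n / 2)
  m <- fit_classifier(classifier_spec("random_forest", n_trees = 1, seed = 2), X, y)
  ti <- ranger::treeInfo(m$fit, 1)
  skip_if(sum(!ti$terminal) != 1, "forest did not produce a single stump")
  exact <- attribute_forest(m, X[1:4, ])
  mc <- attribute_forest(m, X[1:4, ], method = "sampling", n_draws = 300, seed = 8)
  expect_equal(mc$contributions, exact$contributions, tolerance = 0.05)
  expect_equal(mc$n_draws, 300L)
})

test_that("positional and block importances partition the total attribution", {
  f <- fit_flat_forest(n = 100, p = 8, n_trees = 30, seed = 13, informative = c(3, 4))
  at <- attribute_forest(f$model, f$X)
  lengths <- rep(4L, nrow(f$X)) # provenance positions 1..4
  imp <- importance_by_position(at, lengths)
  blk <- importance_by_block(at)
  total <- sum(abs(at$contributions))
  expect_equal(sum(imp$raw), total)
  expect_equal(sum(blk), total)
  expect_equal(imp$normalized, imp$raw / nrow(f$X)) # all long enough here

  # mixed lengths: short peptides only count where they reach
  lengths2 <- c(rep(2L, 50), rep(4L, 50))
  imp2 <- importance_by_position(at, lengths2)
  expect_equal(imp2$n_eligible, c(100, 100, 50, 50))
  impx <- importance_by_position(at, lengths2, mode = "exact_length")
  expect_equal(impx$n_eligible, c(0, 50, 0, 50))
  expect_true(is.na(impx$normalized[1]))
})

test_that("planted positional signal is recovered at toy scale", {
  ds <- small_dataset(n = 150, effect = 3, seed = 61)
  pl <- pipeline_spec("combined", "flatten", "random_forest", n_trees = 150, seed = 61)
  X <- build_features(pl, ds)
  m <- fit_classifier(classifier_spec("random_forest", n_trees = 150, seed = 61),
                      X, ds$records$expressed)
  at <- attribute_forest(m, X)
  imp <- importance_by_position(at, ds$records$length)
  top3 <- sort(imp$position[order(-imp$normalized)][1:3])
  expect_equal(top3, c(7L, 8L, 9L))
  blk <- importance_by_block(at)
  expect_equal(names(which.max(blk)), "single")
})

test_that("pLDDT comparison by prediction outcome behaves at both extremes", {
  set.seed(67)
  n <- 150
  plddt <- rnorm(n, 75, 8)
  labels <- rbinom(n, 1, 0.5) == 1
  # all correct: test skipped
  allc <- compare_plddt_by_outcome(plddt, as.numeric(labels), labels)
  expect_true(allc$skipped)
  expect_equal(allc$n_incorrect, 0L)

  # independent correctness: p should not be extreme
  pred <- rbinom(n, 1, 0.5)
  r0 <- compare_plddt_by_outcome(plddt, pred, labels)
  expect_gt(r0$p_value, 1e-4)

  # shifted pLDDT in the incorrect group: detected
  correct <- pred == labels
  plddt_shift <- plddt + ifelse(correct, 0, 10)
  r1 <- compare_plddt_by_outcome(plddt_shift, pred, labels)
  expect_lt(r1$p_value, 0.01)
  expect_gt(r1$median_incorrect, r1$median_correct)
})

test_that("label-shuffled forests show no spurious positional localization", {
  ds <- small_dataset(n = 150, effect = 3, seed = 83)
  ds$records$expressed <- with_seed_ns(83, sample(ds$records$expressed))
  pl <- pipeline_spec("combined", "flatten", "random_forest", n_trees = 150, seed = 83)
  X <- build_features(pl, ds)
  m <- fit_classifier(classifier_spec("random_forest", n_trees = 150, seed = 83),
                      X, ds$records$expressed)
  at <- attribute_forest(m, X)
  imp <- importance_by_position(at, ds$records$length)
  expect_lt(max(imp$normalized), 3 * median(imp$normalized))
})
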