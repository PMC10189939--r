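#' Classifier heads
#'
#' Two heads are used throughout: a random forest (300 trees by default,
#' otherwise library defaults) on pooled or flattened representations, and
#' an L2-regularized (ridge) logistic regression on kernel-transformed
#' features. Forest scores are the average of per-tree leaf class fractions;
#' logistic scores are the inverse-logit of the linear predictor after the
#' stored training-set standardization. Knottin and non-knottin partitions
#' get fully independent model instances.
#'
#' @name models
NULL

#' Describe a classifier head
#'
#' @param head `"random_forest"` or `"l2_logreg"`.
#' @param n_trees Trees in the forest (default 300).
#' @param regularization_strength Ridge penalty for the logistic head;
#'   `1` corresponds to the common default of unit inverse-regularization
#'   (internally mapped to a glmnet lambda of `strength / n`). The string
#'   `"cv"` selects the strength by internal 5-fold cross-validation over
#'   the grid 10^-3 .. 10^3.
#' @param standardize Center/scale features by training statistics before
#'   the logistic head (zero-variance columns are scaled by 1). Forests
#'   consume raw features (split-based, scale-invariant).
#' @param seed Integer seed; fits are deterministic under it.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(head = c("random_forest", "l2_logreg"),
                            n_trees = 300L, regularization_strength = 1,
                            standardize = TRUE, seed = 1L) {
  head <- match.arg(head)
  if (n_trees < 1L) stop("n_trees must be >= 1", call. = FALSE)
  if (!identical(regularization_strength, "cv") &&
      (!is.numeric(regularization_strength) || regularization_strength <= 0)) {
    stop("regularization_strength must be positive (or \"cv\")", call. = FALSE)
  }
  structure(list(head = head, n_trees = as.integer(n_trees),
                 regularization_strength = regularization_strength,
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "classifier_spec")
}

as_label_factor <- function(y) {
  if (is.factor(y)) y <- as.logical(y == levels(y)[2])
  y <- as.logical(y)
  if (anyNA(y)) stop("labels contain missing values", call. = FALSE)
  factor(ifelse(y, "yes", "no"), levels = c("no", "yes"))
}

check_feature_matrix <- function(X) {
  if (!is.matrix(X) || !is.numeric(X)) stop("X must be a numeric matrix", call. = FALSE)
  if (anyNA(X) || any(!is.finite(X))) stop("X contains missing or non-finite values", call. = FALSE)
  invisible(X)
}

#' Fit a classifier head
#'
#' @param spec A [classifier_spec()].
#' @param X Numeric feature matrix (optionally carrying a `provenance`
#'   attribute describing each column; it is stored and later enforced at
#'   prediction time).
#' @param y Binary labels (logical or 0/1); both classes must be present.
#' @return A `cdp_model` object.
#' @export
fit_classifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  check_feature_matrix(X)
  yf <- as_label_factor(y)
  if (nlevels(droplevels(yf)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  if (nrow(X) != length(yf)) stop("X and y disagree on sample count", call. = FALSE)
  prov <- attr(X, "provenance")

  if (spec$head == "random_forest") {
    colnames(X) <- paste0("f", seq_len(ncol(X)))
    fit <- ranger::ranger(x = X, y = yf, num.trees = spec$n_trees,
                          probability = TRUE, seed = spec$seed,
                          num.threads = 1L)
    model <- list(head = "random_forest", spec = spec, fit = fit,
                  provenance = prov, X_train = X)
  } else {
    n <- nrow(X)
    std <- standardize_stats(X, spec$standardize)
    Xs <- apply_standardize(X, std)
    if (identical(spec$regularization_strength, "cv")) {
      grid <- 10^seq(3, -3, length.out = 13) / n
      foldid <- with_seed(spec$seed, sample(rep_len(1:5, n)))
      cvfit <- glmnet::cv.glmnet(Xs, yf, family = "binomial", alpha = 0,
                                 lambda = grid, foldid = foldid,
                                 standardize = FALSE)
      lambda <- cvfit$lambda.min
    } else {
      lambda <- spec$regularization_strength / n
    }
    fit <- glmnet::glmnet(Xs, yf, family = "binomial", alpha = 0,
                          lambda = lambda, standardize = FALSE, thresh = 1e-10)
    model <- list(head = "l2_logreg", spec = spec, fit = fit, std = std,
                  lambda = lambda, provenance = prov)
  }
  class(model) <- "cdp_model"
  model
}

standardize_stats <- function(X, enabled) {
  if (!enabled) return(NULL)
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1 # zero-variance columns scaled by 1
  list(mu = mu, sd = sdv)
}

apply_standardize <- function(X, std) {
  if (is.null(std)) return(X)
  sweep(sweep(X, 2, std$mu, "-"), 2, std$sd, "/")
}

#' Predict expression probabilities
#'
#' @param model A fitted `cdp_model`.
#' @param X Feature matrix whose column provenance must match the training
#'   features.
#' @return Numeric vector of probabilities of the "expressed" class.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "cdp_model"))
  check_feature_matrix(X)
  prov <- attr(X, "provenance")
  if (!is.null(model$provenance) || !is.null(prov)) {
    if (!isTRUE(all.equal(model$provenance, prov, check.attributes = FALSE))) {
      stop("feature provenance does not match the training features", call. = FALSE)
    }
  }
  if (model$head == "random_forest") {
    colnames(X) <- paste0("f", seq_len(ncol(X)))
    p <- predict(model$fit, data = X, num.threads = 1L)$predictions
    unname(p[, "yes"])
  } else {
    Xs <- apply_standardize(X, model$std)
    as.numeric(predict(model$fit, newx = Xs, type = "response"))
  }
}

#' Save / load a fitted model
#'
#' Serializes the full model state (including stored standardization
#' statistics and feature provenance) to one file; loading restores
#' bit-identical predictions.
#'
#' @param model A `cdp_model`.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cdp_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "cdp_model"))
  model
}
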