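#' Pipeline specifications
#'
#' A pipeline names the three stages between stored representations and a
#' probability of expression: which representation block to use, how to turn
#' the per-residue matrix into a fixed-size feature vector, and which
#' classifier head consumes it.
#'
#' * `representation`: one of the stored blocks (`"single"`,
#'   `"pair_reduced"`, `"msa"`, `"structure"`, a pre-pooled embedding such
#'   as `"seqvec"` / `"proteinfer"`), or `"combined"` for the
#'   1152-channel concatenation of the four structure-prediction blocks.
#' * `summarizer`: `"mean_pool"` (one value per channel, true residues
#'   only), `"rocket"` (zero-pad to `max_len`, then the random kernel
#'   transform), or `"flatten"` (zero-pad and flatten position-by-channel,
#'   the input used for positional attribution).
#' * `head`: `"random_forest"`, `"l2_logreg"`, or the two diagnostic heads
#'   `"oracle"` (scores equal the true held-out labels) and `"random"`
#'   (uniform random scores), which exist for calibrating the evaluation
#'   machinery itself.
#'
#' @param representation Representation block name.
#' @param summarizer Feature summarizer.
#' @param head Classifier head.
#' @param n_kernels Kernels for the `"rocket"` summarizer (default 10000).
#' @param max_len Padded residue count (default 50).
#' @param n_trees,regularization_strength,standardize Passed to
#'   [classifier_spec()].
#' @param channel_mode Kernel channel sampling, see [generate_kernels()].
#' @param seed Integer seed driving kernel generation and head fitting.
#' @return A `pipeline_spec` list.
#' @export
pipeline_spec <- function(representation = "combined",
                          summarizer = c("mean_pool", "rocket", "flatten"),
                          head = c("random_forest", "l2_logreg", "oracle", "random"),
                          n_kernels = 10000L, max_len = 50L, n_trees = 300L,
                          regularization_strength = 1, standardize = TRUE,
                          channel_mode = "subset", seed = 1L) {
  structure(list(representation = representation,
                 summarizer = match.arg(summarizer), head = match.arg(head),
                 n_kernels = as.integer(n_kernels), max_len = as.integer(max_len),
                 n_trees = as.integer(n_trees),
                 regularization_strength = regularization_strength,
                 standardize = isTRUE(standardize), channel_mode = channel_mode,
                 seed = as.integer(seed)),
            class = "pipeline_spec")
}

sample_block <- function(blocks, representation) {
  if (representation == "combined") {
    concat_blocks(blocks$single, blocks$pair_reduced, blocks$msa, blocks$structure,
                  check_widths = FALSE)
  } else {
    b <- blocks[[representation]]
    if (is.null(b)) stop("representation block not in container: ", representation,
                         call. = FALSE)
    b
  }
}

#' Build the feature matrix a pipeline consumes
#'
#' The summarizer runs identically for every sample and uses no label
#' information, so features may be built once on the full dataset and
#' reused across folds without leakage.
#'
#' @param pipeline A [pipeline_spec()].
#' @param dataset A `cdp_dataset` (records + representation container), e.g.
#'   from [generate_cdp_data()].
#' @return Numeric feature matrix with a `provenance` attribute; for the
#'   `"rocket"` summarizer the generated [generate_kernels()] bank is
#'   attached as `attr(, "kernel_bank")`.
#' @export
build_features <- function(pipeline, dataset) {
  stopifnot(inherits(pipeline, "pipeline_spec"))
  container <- dataset$container
  ids <- dataset$records$accession
  if (is.null(container)) stop("dataset has no representation container", call. = FALSE)
  mats <- lapply(container[ids], sample_block, representation = pipeline$representation)

  if (pipeline$summarizer == "mean_pool") {
    X <- do.call(rbind, lapply(mats, mean_pool))
    dimnames(X) <- NULL
    block <- attr(mats[[1]], "block_of_channel") %||% rep(pipeline$representation, ncol(X))
    prov <- data.frame(block = block, position = NA_integer_, channel = seq_len(ncol(X)))
  } else if (pipeline$summarizer == "flatten") {
    padded <- lapply(mats, pad_to, max_len = pipeline$max_len)
    # position-major flattening: columns (p-1)*D + c
    X <- do.call(rbind, lapply(padded, function(m) as.vector(t(m))))
    dimnames(X) <- NULL
    D <- ncol(mats[[1]])
    block <- attr(mats[[1]], "block_of_channel") %||% rep(pipeline$representation, D)
    prov <- data.frame(block = rep(block, times = pipeline$max_len),
                       position = rep(seq_len(pipeline$max_len), each = D),
                       channel = rep(seq_len(D), times = pipeline$max_len))
  } else { # rocket
    padded <- lapply(mats, pad_to, max_len = pipeline$max_len)
    bank <- generate_kernels(pipeline$n_kernels, pipeline$max_len, ncol(mats[[1]]),
                             seed = pipeline$seed, channel_mode = pipeline$channel_mode)
    X <- rocket_transform(padded, bank)
    prov <- attr(X, "provenance")
    attr(X, "kernel_bank") <- bank
  }
  attr(X, "provenance") <- prov
  X
}

# Fit on train rows and score test rows, dispatching the diagnostic heads.
# The "random" head draws from the current RNG stream.
fit_and_score <- function(pipeline, X, y, train, test) {
  if (pipeline$head == "oracle") return(as.numeric(y[test]))
  if (pipeline$head == "random") return(runif(length(test)))
  spec <- classifier_spec(head = pipeline$head, n_trees = pipeline$n_trees,
                          regularization_strength = pipeline$regularization_strength,
                          standardize = pipeline$standardize, seed = pipeline$seed)
  Xtr <- X[train, , drop = FALSE]
  attr(Xtr, "provenance") <- attr(X, "provenance")
  Xte <- X[test, , drop = FALSE]
  attr(Xte, "provenance") <- attr(X, "provenance")
  model <- fit_classifier(spec, Xtr, y[train])
  predict_scores(model, Xte)
}
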