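#' Per-residue representation processing
#'
#' A representation block is a numeric L x D matrix (L residues, D channels).
#' The four structure-prediction blocks have fixed widths: `single` 384,
#' `pair_reduced` 128, `msa` 256, `structure` 384; their concatenation is the
#' 1152-channel `combined` block. Classifier heads consume either the
#' mean-pooled vector (one value per channel) or the zero-padded 50 x D
#' tensor.
#'
#' @name representations
NULL

#' Select the structure-prediction run with the highest mean pLDDT
#'
#' Structure predictors are typically run as several models per peptide;
#' only the run whose per-residue confidence (pLDDT) track has the highest
#' arithmetic mean is carried forward. Ties break to the lowest run index,
#' so selection is deterministic and permutation-stable up to that rule.
#'
#' @param runs List of candidate runs, each a list with elements `plddt`
#'   (numeric vector, values in \[0, 100\]) and arbitrary representation
#'   blocks.
#' @return The selected run, with `attr(, "run_index")` and
#'   `attr(, "mean_plddt")` recorded.
#' @export
select_best_run <- function(runs) {
  if (!is.list(runs) || length(runs) == 0L) stop("empty run set", call. = FALSE)
  means <- vapply(runs, function(r) mean(r$plddt), numeric(1))
  if (anyNA(means)) stop("every run needs a plddt track", call. = FALSE)
  i <- which.max(means) # first maximum = lowest-index tie break
  out <- runs[[i]]
  attr(out, "run_index") <- i
  attr(out, "mean_plddt") <- means[i]
  out
}

#' Reduce a raw pair tensor to per-residue features
#'
#' The raw pair representation is an L x L x C tensor; it is collapsed to an
#' L x C matrix by averaging over the first axis: `out[j, c] = mean_i
#' pair[i, j, c]`.
#'
#' @param pair Numeric L x L x C array (first two dimensions equal).
#' @return Numeric L x C matrix.
#' @export
reduce_pair <- function(pair) {
  d <- dim(pair)
  if (length(d) != 3L || d[1] != d[2]) {
    stop("pair tensor must be L x L x C with equal first two dimensions", call. = FALSE)
  }
  colMeans(pair, dims = 1L)
}

#' Concatenate the four per-residue representation blocks
#'
#' Channel order is `single` (1-384), `pair_reduced` (385-512), `msa`
#' (513-768), `structure` (769-1152); with canonical widths the result has
#' 1152 channels. A block map is attached so any combined channel can be
#' traced back to its source block for interpretability.
#'
#' @param single,pair_reduced,msa,structure Numeric L x D matrices sharing L.
#' @param check_widths Enforce canonical channel widths (default `TRUE`).
#' @return L x (sum of widths) matrix with attributes `block_map`
#'   (data.frame: block, start, end) and `block_of_channel` (character
#'   vector, one block name per channel).
#' @export
concat_blocks <- function(single, pair_reduced, msa, structure, check_widths = TRUE) {
  blocks <- list(single = single, pair_reduced = pair_reduced,
                 msa = msa, structure = structure)
  Ls <- vapply(blocks, nrow, integer(1))
  if (length(unique(Ls)) != 1L) {
    stop("blocks disagree on residue count: ",
         paste(sprintf("%s=%d", names(Ls), Ls), collapse = ", "), call. = FALSE)
  }
  if (check_widths) {
    for (bn in names(blocks)) {
      if (ncol(blocks[[bn]]) != CANONICAL_WIDTHS[[bn]]) {
        stop(sprintf("block '%s' has %d channels, expected %d",
                     bn, ncol(blocks[[bn]]), CANONICAL_WIDTHS[[bn]]), call. = FALSE)
      }
    }
  }
  out <- do.call(cbind, blocks)
  dimnames(out) <- NULL
  w <- vapply(blocks, ncol, integer(1))
  end <- cumsum(w)
  attr(out, "block_map") <- data.frame(block = names(blocks),
                                       start = c(1L, head(end, -1) + 1L), end = end)
  attr(out, "block_of_channel") <- rep(names(blocks), times = w)
  out
}

#' Zero-pad a representation to a fixed residue count
#'
#' Padding is appended at the C-terminal end (trailing rows), preserving
#' N-terminal position indices. Longer inputs are an error, never truncated.
#'
#' @param rep Numeric L x D matrix, L <= `max_len`.
#' @param max_len Target residue count (default 50, the upper end of the
#'   admitted CDP length range).
#' @return `max_len` x D matrix with `attr(, "true_length") = L`; rows past
#'   L are exactly zero. Block-map attributes are carried over.
#' @export
pad_to <- function(rep, max_len = 50L) {
  L <- nrow(rep)
  if (L > max_len) {
    stop(sprintf("representation has %d residues, more than max_len = %d (no truncation)",
                 L, max_len), call. = FALSE)
  }
  out <- matrix(0, nrow = max_len, ncol = ncol(rep))
  out[seq_len(L), ] <- rep
  attr(out, "true_length") <- L
  attr(out, "block_map") <- attr(rep, "block_map")
  attr(out, "block_of_channel") <- attr(rep, "block_of_channel")
  out
}

#' Mean-pool a representation over residues
#'
#' Averages each channel over the true residues only: pad rows added by
#' [pad_to()] are excluded (pooling and padding commute under this rule).
#'
#' @param rep Numeric L x D matrix, optionally carrying a `true_length`
#'   attribute from [pad_to()].
#' @return Numeric vector of length D.
#' @export
mean_pool <- function(rep) {
  L <- attr(rep, "true_length") %||% nrow(rep)
  if (L < 1L) stop("cannot pool an empty representation", call. = FALSE)
  colMeans(rep[seq_len(L), , drop = FALSE])
}
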