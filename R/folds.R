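#' Balanced stratified fold plans
#'
#' Records are stratified into the four knottin-by-expressed cells; within
#' each stratum they are shuffled by the seed and dealt round-robin to the k
#' folds, so per-stratum fold counts differ by at most one. The plan depends
#' only on (records, k, seed), which is the "same shuffle" contract: the
#' identical plan can be reused across representation types so model
#' comparisons share folds.
#'
#' @param records [peptide_records] data.frame with non-missing
#'   `is_knottin` and `expressed` (either flag constant is fine; that
#'   stratum cell is simply empty and skipped with a warning).
#' @param k Number of folds (>= 2, default 10).
#' @param seed Integer seed.
#' @return A `fold_plan`: list with `k`, `assignment` (integer fold index
#'   per record), `strata` (factor) and `seed`.
#' @export
make_balanced_folds <- function(records, k = 10L, seed = 1L) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  n <- nrow(records)
  strata <- interaction(
    factor(records$is_knottin, levels = c(FALSE, TRUE), labels = c("non_knottin", "knottin")),
    factor(records$expressed, levels = c(FALSE, TRUE), labels = c("not_expressed", "expressed")),
    drop = FALSE, sep = ":")
  if (anyNA(strata)) stop("records must have is_knottin and expressed set", call. = FALSE)
  empty <- setdiff(levels(strata), levels(droplevels(strata)))
  if (length(empty)) {
    warning("empty stratum cell(s) skipped: ", paste(empty, collapse = ", "), call. = FALSE)
  }
  assignment <- integer(n)
  with_seed(seed, {
    for (s in levels(droplevels(strata))) {
      idx <- which(strata == s)
      if (length(idx) < k) {
        warning(sprintf("stratum '%s' has %d records, fewer than k = %d; some folds lack it",
                        s, length(idx), k), call. = FALSE)
      }
      idx <- idx[sample.int(length(idx))]
      assignment[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(list(k = as.integer(k), assignment = assignment,
                 strata = strata, seed = as.integer(seed)),
            class = "fold_plan")
}

# One stratified train/validation split (train_fraction in the training
# set), using the same four-cell stratification as the fold plans. Draws
# from the current RNG stream.
stratified_split <- function(records, train_fraction = 0.9) {
  strata <- interaction(records$is_knottin, records$expressed, drop = TRUE)
  test <- integer(0)
  for (s in levels(strata)) {
    idx <- which(strata == s)
    n_test <- max(1L, round((1 - train_fraction) * length(idx)))
    test <- c(test, idx[sample.int(length(idx), n_test)])
  }
  list(train = setdiff(seq_len(nrow(records)), test), test = sort(test))
}
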