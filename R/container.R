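#' Representation containers
#'
#' Per-residue representations are stored in a directory container: one
#' subdirectory per accession holding a `meta.json` (accession, residue
#' count, block dimensions) and one numeric TSV per representation block
#' (`single` L x 384, `pair` L x L x 128 raw or `pair_reduced` L x 128,
#' `msa` L x 256, `structure` L x 384, `plddt` length-L vector). All writes
#' are deterministic (no timestamps), so identical inputs produce
#' byte-identical containers. A raw `pair` tensor is reduced to L x 128 on
#' load (mean over its first axis) and tagged with `attr(, "pair_dialect") =
#' "raw"`; a pre-reduced matrix is accepted and tagged `"reduced"`.
#'
#' @name representation_container
NULL

CANONICAL_WIDTHS <- c(single = 384L, pair_reduced = 128L, msa = 256L,
                      structure = 384L, seqvec = 1024L, proteinfer = 1100L)

#' Write a representation container
#'
#' @param container Named list: accession -> list of blocks. Each block is a
#'   numeric L x D matrix (a raw `pair` element may be an L x L x D array);
#'   `plddt` is a numeric vector of length L.
#' @param path Directory to create/overwrite.
#' @export
write_representation_container <- function(container, path) {
  stopifnot(is.list(container), !is.null(names(container)))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (acc in names(container)) {
    blocks <- container[[acc]]
    d <- file.path(path, acc)
    dir.create(d, showWarnings = FALSE)
    dims <- list()
    L <- NA_integer_
    for (bn in names(blocks)) {
      b <- blocks[[bn]]
      if (bn == "plddt") {
        dims[[bn]] <- length(b)
        L <- length(b)
        data.table::fwrite(data.table::data.table(plddt = as.numeric(b)),
                           file.path(d, "plddt.tsv"), sep = "\t", col.names = FALSE)
      } else if (is.matrix(b)) {
        dims[[bn]] <- dim(b)
        if (is.na(L)) L <- nrow(b)
        data.table::fwrite(data.table::as.data.table(b),
                           file.path(d, paste0(bn, ".tsv")), sep = "\t", col.names = FALSE)
      } else if (is.array(b) && length(dim(b)) == 3L) {
        dims[[bn]] <- dim(b)
        flat <- do.call(rbind, lapply(seq_len(dim(b)[1]), function(i) b[i, , , drop = TRUE]))
        data.table::fwrite(data.table::as.data.table(flat),
                           file.path(d, paste0(bn, ".tsv")), sep = "\t", col.names = FALSE)
      } else {
        stop(sprintf("block '%s' of '%s' is neither matrix, 3-d array nor plddt vector", bn, acc),
             call. = FALSE)
      }
    }
    meta <- list(accession = acc, length = L, blocks = dims)
    jsonlite::write_json(meta, file.path(d, "meta.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

read_block_tsv <- function(file, nrow_expect = NULL) {
  m <- as.matrix(data.table::fread(file, header = FALSE, sep = "\t", data.table = FALSE))
  dimnames(m) <- NULL
  m
}

#' Read a representation container
#'
#' Loads the requested accessions, validating every block's stored shape
#' (and, when `lengths` is supplied, the residue count against the sequence
#' length). Raw pair tensors are reduced on load via [reduce_pair()].
#'
#' @param path Container directory written by
#'   [write_representation_container()].
#' @param ids Character vector of accessions to load.
#' @param lengths Optional named integer vector (accession -> sequence
#'   length) to cross-check residue counts.
#' @param strict Validate canonical channel widths for canonically named
#'   blocks (default `TRUE`).
#' @return Named list: accession -> list of block matrices plus `plddt`.
#' @export
read_representation_container <- function(path, ids, lengths = NULL, strict = TRUE) {
  have <- dir.exists(file.path(path, ids))
  if (!all(have)) {
    stop("accession(s) missing from container: ", paste(ids[!have], collapse = ", "),
         call. = FALSE)
  }
  out <- vector("list", length(ids))
  names(out) <- ids
  for (acc in ids) {
    d <- file.path(path, acc)
    meta <- jsonlite::read_json(file.path(d, "meta.json"), simplifyVector = TRUE)
    L <- as.integer(meta$length)
    if (!is.null(lengths) && !is.na(lengths[acc]) && lengths[acc] != L) {
      stop(sprintf("record '%s': container has %d residues but sequence length is %d",
                   acc, L, lengths[acc]), call. = FALSE)
    }
    blocks <- list()
    for (bn in names(meta$blocks)) {
      dm <- as.integer(unlist(meta$blocks[[bn]]))
      f <- file.path(d, paste0(bn, ".tsv"))
      if (bn == "plddt") {
        v <- read_block_tsv(f)[, 1]
        if (length(v) != L) {
          stop(sprintf("record '%s': plddt track has %d values, expected %d", acc, length(v), L),
               call. = FALSE)
        }
        blocks$plddt <- as.numeric(v)
        next
      }
      m <- read_block_tsv(f)
      if (length(dm) == 3L) { # raw pair tensor stored as (L*L) x C
        if (!identical(dim(m), c(dm[1] * dm[2], dm[3])) || dm[1] != dm[2] || dm[1] != L) {
          stop(sprintf("record '%s': block '%s' shape mismatch", acc, bn), call. = FALSE)
        }
        arr <- array(NA_real_, dm)
        for (i in seq_len(dm[1])) arr[i, , ] <- m[((i - 1) * dm[2] + 1):(i * dm[2]), ]
        red <- reduce_pair(arr)
        attr(red, "pair_dialect") <- "raw"
        blocks$pair_reduced <- red
        next
      }
      if (!identical(dim(m), dm)) {
        stop(sprintf("record '%s': block '%s' stored shape disagrees with meta", acc, bn),
             call. = FALSE)
      }
      if (nrow(m) != L) {
        stop(sprintf("record '%s': block '%s' has %d rows but sequence length is %d",
                     acc, bn, nrow(m), L), call. = FALSE)
      }
      tag <- if (bn == "pair") "pair_reduced" else bn
      if (strict && tag %in% names(CANONICAL_WIDTHS) && ncol(m) != CANONICAL_WIDTHS[[tag]]) {
        stop(sprintf("record '%s': block '%s' has %d channels, expected %d",
                     acc, tag, ncol(m), CANONICAL_WIDTHS[[tag]]), call. = FALSE)
      }
      if (bn == "pair") attr(m, "pair_dialect") <- "reduced"
      blocks[[tag]] <- m
    }
    out[[acc]] <- blocks
  }
  out
}

#' Write per-record prediction scores
#'
#' Tab-separated columns `accession`, `partition`, `score`,
#' `predicted_label` (1 when score >= 0.5) and `true_label` (empty when
#' unknown), in input row order.
#'
#' @param records [peptide_records] data.frame.
#' @param scores Numeric vector in \[0, 1\], one per record.
#' @param path Output path.
#' @export
write_predictions <- function(records, scores, path) {
  stopifnot(nrow(records) == length(scores))
  if (anyNA(scores) || any(scores < 0 | scores > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  out <- data.frame(
    accession = records$accession,
    partition = ifelse(is.na(records$is_knottin), "",
                       ifelse(records$is_knottin, "knottin", "non_knottin")),
    score = scores,
    predicted_label = as.integer(scores >= 0.5),
    true_label = ifelse(is.na(records$expressed), "", as.integer(records$expressed))
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

#' Read a predictions file written by [write_predictions()]
#' @param path Predictions TSV.
#' @return data.frame with the written columns (`true_label` is `NA` where
#'   it was empty).
#' @export
read_predictions <- function(path) {
  data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE,
                    na.strings = "")
}
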