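#' Peptide label tables
#'
#' A peptide record table holds one row per cysteine-dense peptide (CDP):
#' a UniProt-style accession, the amino-acid sequence, whether the peptide is
#' a knottin (UniProt keyword KW-0960), and the observed expression outcome in
#' a mammalian (HEK293) screen. The admitted length range is 30-50 residues;
#' out-of-range or non-standard-alphabet records are flagged (`admitted ==
#' FALSE`) and kept, never silently dropped.
#'
#' @name peptide_records
NULL

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

parse_binary_column <- function(x, name) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  out <- rep(NA, length(x))
  out[x %in% c("1", "TRUE", "true", "T", "yes")] <- TRUE
  out[x %in% c("0", "FALSE", "false", "F", "no")] <- FALSE
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop(sprintf("column '%s' contains non-binary values (e.g. '%s')",
                 name, x[which(bad)[1]]), call. = FALSE)
  }
  out
}

#' Assemble and validate a peptide record table
#'
#' Deduplicates on the (accession, sequence) pair keeping the first
#' occurrence, warns about accessions that reappear with a different sequence,
#' and flags records whose sequence falls outside the 30-50 aa admitted range
#' or uses letters outside the 20 standard amino acids.
#'
#' @param df data.frame with columns `accession`, `sequence` and optionally
#'   `is_knottin`, `expressed` (logical, `NA` allowed).
#' @return A `peptide_records` data.frame with columns `accession`,
#'   `sequence`, `is_knottin`, `expressed`, `length`, `in_range`,
#'   `valid_alphabet`, `admitted`.
#' @export
as_peptide_records <- function(df) {
  stopifnot(is.data.frame(df), all(c("accession", "sequence") %in% names(df)))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$accession <- as.character(df$accession)
  df$sequence <- toupper(trimws(as.character(df$sequence)))
  if (any(!nzchar(df$sequence))) stop("empty sequence in record table", call. = FALSE)
  if (is.null(df$is_knottin)) df$is_knottin <- NA
  if (is.null(df$expressed)) df$expressed <- NA
  df$is_knottin <- as.logical(df$is_knottin)
  df$expressed <- as.logical(df$expressed)

  key <- paste(df$accession, df$sequence, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    cdp_log(sprintf("removed %d duplicate (accession, sequence) entr%s; %d records kept",
                    sum(dup), if (sum(dup) == 1L) "y" else "ies", sum(!dup)))
  }
  df <- df[!dup, , drop = FALSE]

  same_acc <- duplicated(df$accession)
  if (any(same_acc)) {
    warning(sprintf("%d accession(s) reappear with a different sequence; kept as distinct records (e.g. '%s')",
                    sum(same_acc), df$accession[which(same_acc)[1]]), call. = FALSE)
  }

  df$length <- nchar(df$sequence)
  df$in_range <- df$length >= 30L & df$length <= 50L
  letters_ok <- function(s) all(strsplit(s, "")[[1]] %in% AA_ALPHABET)
  df$valid_alphabet <- vapply(df$sequence, letters_ok, logical(1), USE.NAMES = FALSE)
  df$admitted <- df$in_range & df$valid_alphabet
  if (any(!df$in_range)) {
    warning(sprintf("%d record(s) outside the 30-50 aa range; flagged (admitted = FALSE), not dropped",
                    sum(!df$in_range)), call. = FALSE)
  }
  if (any(!df$valid_alphabet)) {
    warning(sprintf("%d record(s) use non-standard amino-acid letters; flagged, not dropped",
                    sum(!df$valid_alphabet)), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("peptide_records", "data.frame")
  df
}

#' Read a peptide label table from CSV/TSV
#'
#' The file must have a header with columns `accession`, `sequence`,
#' `knottin`, `expressed` (comma or tab delimited, auto-detected; the two
#' flag columns take values 0/1 or empty for unknown). Exact duplicate
#' entries -- same accession and same sequence -- are removed, first
#' occurrence kept, and the removal count is logged.
#'
#' @param path Path to the label table.
#' @return A [peptide_records] data.frame.
#' @export
read_label_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "auto",
                          colClasses = "character", na.strings = c("", "NA"),
                          data.table = FALSE)
  need <- c("accession", "sequence", "knottin", "expressed")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("label table is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(dt) == 0L) {
    out <- data.frame(accession = character(), sequence = character(),
                      is_knottin = logical(), expressed = logical(),
                      length = integer(), in_range = logical(),
                      valid_alphabet = logical(), admitted = logical())
    class(out) <- c("peptide_records", "data.frame")
    return(out)
  }
  as_peptide_records(data.frame(
    accession = dt$accession,
    sequence = dt$sequence,
    is_knottin = parse_binary_column(dt$knottin, "knottin"),
    expressed = parse_binary_column(dt$expressed, "expressed"),
    stringsAsFactors = FALSE
  ))
}

#' Write a peptide label table
#'
#' Inverse of [read_label_table()]; deterministic, tab-separated, no
#' timestamps, so identical inputs yield byte-identical files.
#'
#' @param records [peptide_records] data.frame.
#' @param path Output path.
#' @export
write_label_table <- function(records, path) {
  out <- data.frame(
    accession = records$accession,
    sequence = records$sequence,
    knottin = ifelse(is.na(records$is_knottin), "", as.integer(records$is_knottin)),
    expressed = ifelse(is.na(records$expressed), "", as.integer(records$expressed))
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

#' Read peptide sequences from FASTA
#'
#' Alternative sequence source for prediction-only use: sequences are read
#' from FASTA (accession = first whitespace-delimited token of the header)
#' and, if a label table is given, joined to it by accession; sequences with
#' no label row get missing flags.
#'
#' @param path FASTA file of amino-acid sequences.
#' @param labels Optional [peptide_records] table supplying `is_knottin` /
#'   `expressed` by accession.
#' @return A [peptide_records] data.frame.
#' @export
read_fasta_records <- function(path, labels = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package", call. = FALSE)
  }
  aa <- Biostrings::readAAStringSet(path)
  acc <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  df <- data.frame(accession = acc, sequence = as.character(aa),
                   stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    i <- match(df$accession, labels$accession)
    df$is_knottin <- labels$is_knottin[i]
    df$expressed <- labels$expressed[i]
  }
  as_peptide_records(df)
}

#' Partition records into knottin and non-knottin sets
#'
#' Splits the admitted records on the knottin flag and reports per-partition
#' expressed / not-expressed counts with percentages (one decimal), the
#' summary used to check class balance before fold construction.
#'
#' @param records [peptide_records] data.frame; every row must have a
#'   non-missing `is_knottin` flag.
#' @return A `dataset_partition` list with elements `knottins`,
#'   `non_knottins` (record subsets) and `summary` (data.frame with columns
#'   `partition`, `n`, `n_expressed`, `n_not_expressed`, `pct_expressed`,
#'   `pct_not_expressed`; percentages `NA` for an empty partition).
#' @export
partition_dataset <- function(records) {
  if (anyNA(records$is_knottin)) {
    stop("all records must have is_knottin set before partitioning", call. = FALSE)
  }
  kn <- records[records$is_knottin, , drop = FALSE]
  nk <- records[!records$is_knottin, , drop = FALSE]
  row_for <- function(df, name) {
    n <- nrow(df)
    ne <- sum(df$expressed, na.rm = TRUE)
    nn <- sum(!df$expressed, na.rm = TRUE)
    data.frame(partition = name, n = n, n_expressed = ne, n_not_expressed = nn,
               pct_expressed = if (n > 0L) round(100 * ne / n, 1) else NA_real_,
               pct_not_expressed = if (n > 0L) round(100 * nn / n, 1) else NA_real_)
  }
  out <- list(knottins = kn, non_knottins = nk,
              summary = rbind(row_for(nk, "non_knottin"), row_for(kn, "knottin")))
  class(out) <- "dataset_partition"
  out
}

#' @export
print.dataset_partition <- function(x, ...) {
  cat("Dataset partition (knottin vs non-knottin)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
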