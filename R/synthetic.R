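#' Synthetic CDP datasets
#'
#' The generator emulates the structure of a real per-residue embedding
#' dataset -- variable peptide lengths, four representation blocks, a pLDDT
#' track -- with a controllable planted class signal, so that every stage of
#' the pipeline (ingestion, pooling, kernel transform, heads, evaluation,
#' attribution) is testable without running any structure-prediction model.
#' Background channels are independent standard normal; peptides whose
#' latent class is "expressed" get `effect_size` added at the chosen
#' (positions x channels) cells of the chosen block; observed labels flip
#' with probability `label_noise`. pLDDT tracks are `60 + 35 *
#' plogis(rnorm(L))` clipped to \[0, 100\]. Everything is deterministic
#' under `seed`.
#'
#' Positions are 1-based residue indices anchored at the N-terminus, so
#' trailing-pad conventions never shift them; a C-terminus-anchored signal
#' can be requested with `anchor = "C"`.
#'
#' @param n_samples Number of peptides.
#' @param length_range Inclusive length range (default 30-50, the admitted
#'   CDP range).
#' @param knottin_fraction Probability a peptide is flagged knottin
#'   (default 0.286, the knottin share of the published screen).
#' @param positive_fraction Probability of the positive latent class
#'   (default 0.553, the expressed share of the screen).
#' @param effect_size Planted mean shift (in background SD units) added for
#'   the positive class.
#' @param signal_positions 1-based residue positions carrying the signal
#'   (must fit within the shortest peptide; default 7:9).
#' @param signal_block Block carrying the signal (default `"single"`).
#' @param signal_channels Channels of `signal_block` carrying the signal
#'   (default 1:8).
#' @param label_noise Probability of flipping an observed label.
#' @param anchor `"N"` (default) or `"C"`: end the signal positions count
#'   from.
#' @param block_widths Named channel widths for the four generated blocks;
#'   defaults to the canonical 384/128/256/384. Tests may shrink them.
#' @param seed Integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples, length_range = c(30L, 50L),
                             knottin_fraction = 0.286, positive_fraction = 0.553,
                             effect_size = 1, signal_positions = 7:9,
                             signal_block = "single", signal_channels = 1:8,
                             label_noise = 0, anchor = c("N", "C"),
                             block_widths = c(single = 384L, pair_reduced = 128L,
                                              msa = 256L, structure = 384L),
                             seed = 1L) {
  anchor <- match.arg(anchor)
  stopifnot(n_samples >= 1L, length(length_range) == 2L,
            length_range[1] <= length_range[2],
            knottin_fraction >= 0, knottin_fraction <= 1,
            positive_fraction >= 0, positive_fraction <= 1,
            effect_size >= 0, label_noise >= 0, label_noise < 1)
  if (!signal_block %in% names(block_widths)) {
    stop("signal_block must be one of: ", paste(names(block_widths), collapse = ", "),
         call. = FALSE)
  }
  if (any(signal_positions < 1L) || any(signal_positions > length_range[1])) {
    stop("signal_positions must lie within every generated peptide (1..min length)",
         call. = FALSE)
  }
  if (any(signal_channels < 1L) || any(signal_channels > block_widths[[signal_block]])) {
    stop("signal_channels exceed the width of the signal block", call. = FALSE)
  }
  structure(list(n_samples = as.integer(n_samples),
                 length_range = as.integer(length_range),
                 knottin_fraction = knottin_fraction,
                 positive_fraction = positive_fraction,
                 effect_size = effect_size,
                 signal_positions = as.integer(signal_positions),
                 signal_block = signal_block,
                 signal_channels = as.integer(signal_channels),
                 label_noise = label_noise, anchor = anchor,
                 block_widths = block_widths, seed = as.integer(seed)),
            class = "synthetic_config")
}

random_sequence <- function(len, knottin) {
  s <- sample(AA_ALPHABET, len, replace = TRUE)
  if (knottin) s[sample.int(len, 6L)] <- "C" # cosmetic: knottins carry 6 cysteines
  paste(s, collapse = "")
}

#' Generate a synthetic dataset
#'
#' @param config A [synthetic_config()].
#' @return A `cdp_dataset`: list with `records` (a [peptide_records] table
#'   plus `mean_plddt` and the latent `class_signal` column) and
#'   `container` (accession -> representation blocks + `plddt`), ready for
#'   [build_features()] and interchangeable with containers read from disk.
#' @export
generate_cdp_data <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_samples
    lens <- sample(seq(cfg$length_range[1], cfg$length_range[2]), n, replace = TRUE)
    knottin <- runif(n) < cfg$knottin_fraction
    latent <- runif(n) < cfg$positive_fraction
    flip <- runif(n) < cfg$label_noise
    observed <- xor(latent, flip)
    acc <- sprintf("SYN%05d", seq_len(n))
    seqs <- mapply(random_sequence, lens, knottin)

    container <- vector("list", n)
    names(container) <- acc
    for (i in seq_len(n)) {
      L <- lens[i]
      blocks <- lapply(cfg$block_widths, function(w) matrix(rnorm(L * w), L, w))
      if (latent[i] && cfg$effect_size > 0) {
        pos <- if (cfg$anchor == "N") cfg$signal_positions else L - cfg$signal_positions + 1L
        blocks[[cfg$signal_block]][pos, cfg$signal_channels] <-
          blocks[[cfg$signal_block]][pos, cfg$signal_channels] + cfg$effect_size
      }
      blocks$plddt <- pmin(100, pmax(0, 60 + 35 * plogis(rnorm(L))))
      container[[i]] <- blocks
    }

    records <- suppressWarnings(as_peptide_records(data.frame(
      accession = acc, sequence = unname(seqs),
      is_knottin = knottin, expressed = observed, stringsAsFactors = FALSE)))
    records$class_signal <- latent
    records$mean_plddt <- vapply(container, function(b) mean(b$plddt), numeric(1))
    structure(list(records = records, container = container, config = cfg),
              class = "cdp_dataset")
  })
}

#' @export
print.cdp_dataset <- function(x, ...) {
  cat(sprintf("Synthetic CDP dataset: %d records (%d knottin, %d expressed)%s\n",
              nrow(x$records), sum(x$records$is_knottin),
              sum(x$records$expressed, na.rm = TRUE),
              if (is.null(x$container)) ", no representations" else ""))
  invisible(x)
}

#' Synthetic dataset with the class geometry of the published screen
#'
#' Emits exactly 876 non-knottins (513 expressed) and 351 knottins (165
#' expressed) -- the class counts of the 1227-peptide HEK293 expression
#' screen -- with synthetic sequences and, optionally, synthetic
#' representation blocks. This fixture exercises fold balancing, partition
#' reporting and metric shapes at the real dataset's geometry.
#'
#' @param seed Integer seed.
#' @param with_representations Also generate representation blocks (off by
#'   default: the full-width container for 1227 records is large).
#' @param block_widths Channel widths when representations are generated.
#' @return A `cdp_dataset` (container `NULL` unless requested).
#' @export
simulate_screen_dataset <- function(seed = 1L, with_representations = FALSE,
                                    block_widths = c(single = 384L, pair_reduced = 128L,
                                                     msa = 256L, structure = 384L)) {
  counts <- data.frame(knottin = c(FALSE, FALSE, TRUE, TRUE),
                       expressed = c(TRUE, FALSE, TRUE, FALSE),
                       n = c(513L, 363L, 165L, 186L))
  knottin <- rep(counts$knottin, counts$n)
  expressed <- rep(counts$expressed, counts$n)
  n <- length(knottin)
  with_seed(seed, {
    lens <- sample(30:50, n, replace = TRUE)
    acc <- sprintf("SCR%05d", seq_len(n))
    seqs <- mapply(random_sequence, lens, knottin)
    container <- NULL
    if (with_representations) {
      container <- vector("list", n)
      names(container) <- acc
      for (i in seq_len(n)) {
        L <- lens[i]
        blocks <- lapply(block_widths, function(w) matrix(rnorm(L * w), L, w))
        blocks$plddt <- pmin(100, pmax(0, 60 + 35 * plogis(rnorm(L))))
        container[[i]] <- blocks
      }
    }
    records <- as_peptide_records(data.frame(
      accession = acc, sequence = unname(seqs),
      is_knottin = knottin, expressed = expressed, stringsAsFactors = FALSE))
    if (!is.null(container)) {
      records$mean_plddt <- vapply(container, function(b) mean(b$plddt), numeric(1))
    }
    structure(list(records = records, container = container), class = "cdp_dataset")
  })
}
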