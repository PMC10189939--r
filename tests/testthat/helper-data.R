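# Shared fixtures, all generated in code.

# Run code under a seed without touching the session RNG (internal helper).
with_seed_ns <- function(seed, code) {
  get("with_seed", asNamespace("cdpexpress"))(seed, code)
}

# Small-width synthetic dataset: full pipeline mechanics at toy scale.
small_dataset <- function(n = 60, effect = 2, seed = 7, noise = 0, ...) {
  generate_cdp_data(synthetic_config(
    n_samples = n, effect_size = effect, label_noise = noise, seed = seed,
    block_widths = c(single = 12L, pair_reduced = 6L, msa = 8L, structure = 10L),
    signal_channels = 1:4, ...))
}

# A label table data.frame ready for write/read round trips.
toy_label_df <- function() {
  data.frame(
    accession = c("P001", "P002", "P003"),
    sequence = c(strrep("ACDEF", 7), strrep("GHIKL", 8), strrep("MNPQR", 6)),
    knottin = c(1, 0, 1),
    expressed = c(1, 0, ""),
    stringsAsFactors = FALSE
  )
}

write_toy_label_table <- function(df, path = tempfile(fileext = ".csv"), sep = ",") {
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

# Deterministic small representation set for one peptide.
toy_blocks <- function(L = 35, seed = 1) {
  with_seed <- get("with_seed", asNamespace("cdpexpress"))
  with_seed(seed, list(
    single = matrix(rnorm(L * 384), L, 384),
    pair_reduced = matrix(rnorm(L * 128), L, 128),
    msa = matrix(rnorm(L * 256), L, 256),
    structure = matrix(rnorm(L * 384), L, 384),
    plddt = runif(L, 40, 95)
  ))
}
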