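test_that("generation is bit-identical under a fixed seed and varies across seeds", {
  cfg <- function(s) synthetic_config(n_samples = 12, seed = s,
                                      block_widths = c(single = 6L, pair_reduced = 4L,
                                                       msa = 5L, structure = 6L),
                                      signal_channels = 1:2)
  a <- generate_cdp_data(cfg(3))
  b <- generate_cdp_data(cfg(3))
  expect_identical(a$container, b$container)
  expect_identical(a$records$sequence, b$records$sequence)
  expect_false(identical(generate_cdp_data(cfg(4))$container, a$container))
})

test_that("generated data honors the configured geometry and signal placement", {
  cfg <- synthetic_config(n_samples = 40, effect_size = 5, label_noise = 0,
                          signal_positions = 3:4, signal_block = "msa",
                          signal_channels = 1:3, seed = 71,
                          block_widths = c(single = 6L, pair_reduced = 4L,
                                           msa = 5L, structure = 6L))
  ds <- generate_cdp_data(cfg)
  rec <- ds$records
  expect_true(all(rec$length >= 30 & rec$length <= 50))
  expect_true(all(rec$mean_plddt >= 0 & rec$mean_plddt <= 100))
  # knottin sequences carry at least 6 cysteines
  ncys <- vapply(strsplit(rec$sequence, ""), function(s) sum(s == "C"), numeric(1))
  expect_true(all(ncys[rec$is_knottin] >= 6))
  # with zero label noise the observed label equals the latent class
  expect_equal(rec$expressed, rec$class_signal)
  # planted shift is visible exactly at the configured cells
  pos_mean <- mean(vapply(which(rec$class_signal), function(i) {
    mean(ds$container[[i]]$msa[3:4, 1:3])
  }, numeric(1)))
  neg_mean <- mean(vapply(which(!rec$class_signal), function(i) {
    mean(ds$container[[i]]$msa[3:4, 1:3])
  }, numeric(1)))
  expect_gt(pos_mean, neg_mean + 3)
  off_signal <- mean(vapply(which(rec$class_signal), function(i) {
    mean(ds$container[[i]]$msa[5:10, 4:5])
  }, numeric(1)))
  expect_lt(abs(off_signal), 0.5)
})

test_that("label noise flips the configured fraction on average", {
  cfg <- synthetic_config(n_samples = 400, effect_size = 1, label_noise = 0.25, seed = 73,
                          block_widths = c(single = 2L, pair_reduced = 2L,
                                           msa = 2L, structure = 2L),
                          signal_channels = 1L)
  ds <- generate_cdp_data(cfg)
  flipped <- mean(ds$records$expressed != ds$records$class_signal)
  expect_gt(flipped, 0.15)
  expect_lt(flipped, 0.35)
})

test_that("generated containers pass container validation across seeds", {
  for (seed in 1:10) {
    ds <- small_dataset(n = 5, seed = seed)
    path <- tempfile()
    write_representation_container(ds$container, path)
    back <- read_representation_container(
      path, ds$records$accession,
      lengths = setNames(ds$records$length, ds$records$accession),
      strict = FALSE)
    expect_equal(length(back), 5L)
  }
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(10, signal_positions = 0:2), "signal_positions")
  expect_error(synthetic_config(10, signal_positions = 29:31), "signal_positions")
  expect_error(synthetic_config(10, signal_channels = 1:500), "signal_channels")
  expect_error(synthetic_config(10, signal_block = "nope"), "signal_block")
  expect_error(synthetic_config(10, label_noise = 1), "label_noise")
})

test_that("the screen-shaped dataset reproduces the published class geometry", {
  ds <- simulate_screen_dataset(seed = 5)
  rec <- ds$records
  expect_equal(nrow(rec), 1227L)
  expect_equal(sum(!rec$is_knottin), 876L)
  expect_equal(sum(!rec$is_knottin & rec$expressed), 513L)
  expect_equal(sum(rec$is_knottin), 351L)
  expect_equal(sum(rec$is_knottin & rec$expressed), 165L)

  part <- partition_dataset(rec)
  s <- part$summary
  expect_equal(s$pct_expressed[s$partition == "non_knottin"], 58.6)
  expect_equal(s$pct_expressed[s$partition == "knottin"], 47.0)

  # balanced 10-fold plan: per-stratum fold counts differ by <= 1
  plan <- make_balanced_folds(rec, k = 10, seed = 5)
  tab <- table(plan$assignment, plan$strata)
  expect_lte(max(apply(tab, 2, function(col) diff(range(col)))), 1)
})

test_that("cross-validated AUC is non-decreasing in effect size", {
  aucs <- vapply(c(0, 0.5, 1, 2), function(delta) {
    ds <- small_dataset(n = 120, effect = delta, seed = 79)
    plan <- make_balanced_folds(ds$records, k = 5, seed = 79)
    cross_validate(pipeline_spec("combined", "mean_pool", "random_forest",
                                 n_trees = 100, seed = 79), ds, plan)$mean_auc
  }, numeric(1))
  expect_true(all(diff(aucs) >= -0.03))
  expect_gt(aucs[4], aucs[1])
})
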