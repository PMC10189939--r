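---
title: "Predicting CDP expressibility from per-residue representations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting CDP expressibility from per-residue representations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdpexpress)
```

## The problem

Cysteine-dense peptides (CDPs) are short (here 30-50 residue) peptides
stabilized by several disulfide bridges; knottins are the subclass whose three
interwoven bridges form an inhibitor cystine knot. Whether a given CDP can be
produced recombinantly in mammalian cells is hard to anticipate from sequence
alone, and screening is expensive. `cdpexpress` implements a classification
pipeline that predicts this binary *expressibility* outcome from per-residue
representations emitted by pretrained protein neural networks (a structure
predictor's single / pair / MSA / structure-module embeddings, or pre-pooled
language-model embeddings). The package does **not** run any embedding model:
representations are inputs, supplied through a plain-text container format,
and a synthetic generator produces structurally identical data so that the
whole pipeline is testable end to end without external downloads.

## Data model and ingestion

A peptide record carries an accession, an amino-acid sequence, a knottin flag
(UniProt keyword KW-0960 in real data) and the observed expression label.
Ingestion deduplicates on the **(accession, sequence) pair**, keeping the
first occurrence. Duplicate accessions that reappear with a *different*
sequence are kept as distinct records with a warning: collapsing them would
silently discard data on an ambiguous key. Records outside the 30-50 aa
range, or using non-standard letters, are flagged (`admitted = FALSE`) rather
than dropped -- the tool surfaces out-of-range inputs instead of hiding them.

The knottin / non-knottin partition report gives per-set expressed counts and
percentages at one decimal. On the synthetic replica of the published screen
geometry (876 non-knottins of which 513 expressed; 351 knottins of which 165
expressed) this prints 58.6% and 47.0%.

Representations live in a directory container: one subdirectory per
accession with a `meta.json` and one numeric TSV per block. The pair tensor
is accepted in both dialects -- raw `L x L x 128`, reduced on load by
averaging over the **first** axis (`out[j, c] = mean_i pair[i, j, c]`,
implemented exactly as stated; which axis indexes the "partner" residue in
any given extraction pipeline is the supplier's convention, and the reduction
is symmetric to relabeling only in expectation) -- or pre-reduced `L x 128`.
Both are tagged with their dialect on load.

## Representation processing

* **Best-of-run selection.** When a structure predictor is run as several
  models per peptide, only the run with the highest mean per-residue
  confidence (pLDDT) is carried forward; ties break to the lowest run index
  so selection is deterministic.
* **Concatenation.** The four per-residue blocks are concatenated in the
  fixed order single (384) + pair (128) + MSA (256) + structure (384) = 1152
  channels, with a retained block map so any combined channel can be traced
  back for interpretability.
* **Padding.** Shorter peptides are zero-padded to 50 rows *at the C-terminal
  end*. Trailing padding preserves N-terminal position indices, which keeps
  position-resolved importance profiles anchored at residue 1; a
  C-terminus-anchored planted signal is available in the generator for
  studying the opposite convention.
* **Pooling.** Mean pooling averages each channel over the *true* residues
  only, never over pad rows; pooling before or after padding is therefore
  equivalent, and the tests assert this commutation.

## The random-kernel transform

Mean pooling discards positional information. The alternative summarizer is
a random convolutional kernel transform: a bank of random kernels is
convolved along the residue axis and each kernel's output series is reduced
to two numbers, the proportion of strictly positive values (PPV) and the
maximum, giving `2 x n_kernels` features (20,000 from the default bank of
10,000). Kernel parameters follow the standard recipe for this transform
family: lengths uniform over {7, 9, 11}; standard-normal weights
mean-centered per kernel; bias uniform on [-1, 1]; dilation `floor(2^a)` with
`a` uniform up to `log2((input_length - 1)/(kernel_length - 1))`, which
guarantees the dilated span fits the input; "same" zero-padding on a fair
coin. The original formulation is univariate; for the 1152-channel input
each kernel draws a random channel subset (size log-uniform on
[1, n_channels], one shared bias), the standard multivariate extension. An
`channel_mode = "all"` flag exists for sensitivity analysis. PPV uses strict
`> 0`, so an output of exactly zero counts as non-positive, and zero pad rows
enter the convolution as ordinary zeros (padding happens before the
transform).

Banks are regenerated bit-identically from (seed, n_kernels, input_length,
n_channels) and serialize to JSON with 17-significant-digit doubles so a
frozen transform round-trips exactly. The compiled transform is tested for
exact agreement (1e-10) against a naive per-kernel R loop on randomized
small instances.

## Classifier heads

* **Random forest** (default 300 trees, other hyperparameters at library
  defaults): probability forest, so a peptide's score is the average of
  per-tree leaf class fractions. Forests consume raw pooled or flattened
  features -- splits are scale-invariant.
* **L2-regularized logistic regression** for kernel-transformed features.
  PPV and max features have heterogeneous scales, so columns are standardized
  by training-set statistics stored in the model (zero-variance columns are
  scaled by 1); the decision function is then invariant to affine rescaling
  of inputs. The regularization strength defaults to 1, mapped internally to
  a ridge penalty of `strength / n` (equivalent to the common unit
  inverse-regularization default); `"cv"` selects it on a 10^-3..10^3 grid by
  internal deterministic 5-fold cross-validation. Class weights are
  uniform, matching default behaviour.

Knottin and non-knottin partitions get fully independent model instances --
no parameter sharing -- a two-headed architecture motivated by the two
classes responding to different features.

## Evaluation machinery

**Balanced folds.** Records are stratified into the four knottin-by-expressed
cells; each stratum is shuffled under the seed and dealt round-robin, so
per-stratum fold counts differ by at most one. The plan is a pure function
of (records, k, seed): the *same shuffle* can be reused across
representation types, which is what makes model comparisons paired.

**LOOCV.** One fit per sample; the held-out confidences are aggregated into
a single ROC/AUC, and a confusion matrix at threshold 0.5 yields
sensitivity, specificity, precision, accuracy and F1 (reported at 3
decimals, stored at full precision; a metric with a zero denominator is
reported absent rather than 0/0).

**AUC** is computed from midranks and equals the Mann-Whitney U statistic
over positive/negative score pairs divided by `n1 * n0`; the tests assert
this identity, antisymmetry under score negation, and agreement with brute
force pair counting.

**Model ranking.** Over `n_permutations` (default 50) stratified 90-10
splits shared by all models, models are ranked by validation AUC and mean
ranks computed. Grouping uses the Friedman omnibus test followed by the
Nemenyi critical difference at `alpha = 0.05` -- the standard procedure for
critical-difference diagrams; the result object carries mean ranks, the CD
and the pairwise same-group matrix needed to draw one.

**Paired permutation AUC test.** Two pipelines are scored on the same fold
plan; the observed statistic is the difference of aggregated out-of-fold
AUCs. The exchanged unit under the null is the per-sample score *pair*
(a fold-level swap is available as an option), 10,000 swaps by default, with
+1 Monte-Carlo smoothing `(b + 1)/(m + 1)` so p is never exactly zero.

**Mann-Whitney U** uses midranks; the two-sided p-value is exact by
enumeration of group assignments when the smaller sample has <= 8
observations *and* the enumeration stays below 2e5 arrangements (the extra
guard keeps e.g. an 8-vs-500 comparison from attempting ~10^16
arrangements); otherwise a normal approximation with tie correction and
continuity correction is used. Enumeration over the observed midranks makes
the exact branch valid under ties.

## Attribution

Forest predictions are decomposed into exact per-feature Shapley
contributions with the tree-path algorithm (path-dependent conditioning).
The fitted forest object does not expose per-node training counts, so node
covers are recomputed by routing the training matrix through each tree; the
training features are retained inside forest models for this purpose. Local
accuracy -- base value plus contribution sum equals the predicted
probability -- holds to floating-point precision regardless of the cover
choice, and the compiled implementation is tested for exact agreement with a
brute-force subset-enumeration Shapley oracle on small trees. A Monte-Carlo
permutation-sampling estimator is provided as a generic fallback; note it
marginalizes against a background sample (interventional conditioning) and
therefore only coincides with the exact algorithm when split features are
independent. Attribution targets the probability of the positive
("expressed") class, and is refused for kernel-transformed features: the
transform severs the link between features and residue positions, so only
forests on flattened position-by-channel inputs are attributable.

Positional importance sums absolute contributions per position and
normalizes by the number of peptides *long enough to occupy that position*
(`length >= p`), which corrects exactly the undercounting that trailing
padding induces at C-terminal positions. The literal per-exact-length
normalization is available behind `mode = "exact_length"`. Block importance
sums the same attributions within each representation block; both views
partition the same total absolute attribution, which is asserted in the
tests.

The pLDDT comparison partitions peptides into correctly (TP + TN) and
incorrectly (FP + FN) predicted groups at threshold 0.5 and compares mean
pLDDT between groups with the Mann-Whitney test, reporting group sizes,
medians and interquartile ranges; an empty group skips the test.

## The synthetic generator

The generator emulates the *structure* of the real data, not its
distribution: lengths uniform on [30, 50]; sequences random over the
20-letter alphabet (knottins get 6 cysteines forced, cosmetic only);
independent standard-normal background in all four blocks at canonical
widths; a planted mean shift of `effect_size` at chosen
positions-by-channels of one block for the positive latent class; observed
labels flipped with probability `label_noise`; pLDDT tracks
`60 + 35 * plogis(rnorm(L))` clipped to [0, 100]. Defaults mirror the
published screen where it states them: knottin fraction 0.286 and positive
fraction 0.553 (the screen's class shares), signal at N-terminal positions
7:9 on 8 channels of the single block. Everything is bit-reproducible under
the seed. Because the background is independent noise, passing recovery
tests demonstrates the *mechanics* of the pipeline -- leakage-free folds,
correct pooling and attribution bookkeeping, calibrated tests -- and says
nothing about real embedding covariance, sequence realism, or real-data
AUCs, which require the external embedding dataset and are out of scope.

## Numerical and design choices

* Positions and channels are 1-based throughout the R API.
* Tie-breaks are deterministic everywhere: best-run selection takes the
  lowest index; rank ties are averaged; PPV counts strict positives.
* The recovery study reported by `scripts/acceptance.R` uses n = 300
  peptides at canonical widths with a delta = 2 signal; both the
  cross-validated recovery AUC and the positional attribution use the same
  model family, the forest on the flattened 50 x 1152 combined
  representation. A planted positional signal is exactly the structure the
  flattened forest can exploit and that mean pooling dilutes by the length
  of the peptide -- a contrast the package's ranking machinery is designed
  to expose. The ranking and
  permutation-test calibrations run on reduced-width backgrounds (12/6/8/10
  channels) at n = 160-300: these exercise ranking and test calibration,
  whose difficulty does not grow with channel count.
* Fold plans warn (not fail) when a stratum is smaller than k; CV folds with
  single-class training sets are skipped with a warning; AUC is `NA` for a
  single-class held-out fold and excluded from the mean.
* File writers are timestamp-free and byte-deterministic; kernel banks
  round-trip bit-exactly via 17-digit decimal strings.

## Known limitations

* The synthetic background is i.i.d. normal; real embeddings are strongly
  correlated across channels and positions, so synthetic AUCs do not
  transfer to real data.
* The Monte-Carlo attribution fallback estimates a different conditioning
  than the exact tree-path algorithm under correlated features.
* The exact Mann-Whitney branch is enumeration-bounded as described above.
* Per-exact-length importance normalization leaves most positions absent on
  datasets whose lengths do not cover the full range; the occupancy
  normalization is the default for that reason.
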