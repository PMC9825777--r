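---
title: "Predicting cell-type-specific and shared TF binding sites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cell-type-specific and shared TF binding sites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A transcription factor (TF) assayed by ChIP-seq in two cell types — here
generically "cell A" and "cell B", e.g. two hematopoietic lines — binds
some sites in only one of the two cell types and others in both.  Because
the sequence preference of the factor is the same in both cells,
discriminating *cell-type-specific* from *shared* binding sites
(CSSBS) is much harder than the classic bound-vs-unbound problem and is
thought to be driven largely by the local chromatin context: chromatin
accessibility, histone modifications, cooperating cofactor motifs and 3D
contacts.  `bindspec` implements an end-to-end framework for this
problem:

1. **Differential site selection** (`select_peaks()`): peaks from the two
   cell types are merged, ChIP fragments are counted per merged peak per
   cell type, a negative-binomial test yields a log2 fold-change (B over
   A) and BH-adjusted q-value per peak, and thresholds classify each peak
   as A-specific, B-specific, shared, or abandoned.  Peaks are trimmed to
   600 bp and split by chromosome (chr8 + chr16 test, chr18 validation,
   chrY excluded, rest training) so that train and test sets can never
   overlap positionally.
2. **Feature generation** for a gradient-boosted tree classifier: PWM
   motif scores (top 3 per cofactor motif over both strands), per-assay
   chromatin statistics (min/mean/max per 600 bp peak per cell type plus
   the between-cell difference; 135 features for 15 landscapes),
   Hi-C interaction statistics (counts and distances of the top-20
   interacting 5 kb bins per cell type plus differences; 18 features),
   and optional sequence features (gapped k-mer counts or CNN-derived
   features).
3. **Classifiers**: a boosted-tree model over the feature table and a
   multi-channel CNN over the raw 600 bp window (one-hot DNA plus
   accessibility channels).  Three tasks are supported: A-specific vs
   B-specific (task A), specific vs shared (task B, the headline task),
   and the 3-way problem (task C).  Binary tasks are scored with AUC and
   PRAUC, the 3-way task with balanced accuracy and macro F1.
4. **Interpretation**: reference-based per-position attribution for the
   CNN, exact SHAP values for the tree model, accessibility correlation
   summaries, base-pair Jaccard distances between peak sets, and the
   cross-factor / leave-one-factor-out protocols.

# The differential test

A production-scale pipeline normally delegates this step to a dedicated
differential-count package; `bindspec` ships a self-contained
stand-in so the pipeline runs offline, plus
`read_differential_table()` to import externally computed results.
The built-in test models counts $K \sim \mathrm{NB}(\mu, \alpha)$ with
$\mathrm{Var}(K) = \mu + \alpha\mu^2$:

* **Size factors.** The two count vectors are rescaled by the square root
  of the median per-peak ratio (`size_factors = "median_ratio"`), which
  is robust when a large minority of peaks is truly differential.  With
  `"none"` raw counts are compared — appropriate when libraries are known
  to be depth-matched, e.g. simulations that plant a *global* fold change
  (any size-factor scheme would absorb such a shift, which is the usual
  compositional caveat of count normalization).
* **Dispersion.** One pooled $\alpha$ is estimated by the method of
  moments.  With a single A/B pair per peak, the moment estimate of a
  truly differential peak is inflated by its real effect, so the pooled
  value is the *lower quartile* of the per-peak estimates: robust as long
  as fewer than ~75% of peaks are strongly differential, at the cost of
  being slightly liberal under a pure null.
* **Wald test.** `log2fc = log2((b + 1)/(a + 1))`; the delta-method
  variance of a log NB count is $1/\mu + \alpha$ per condition, giving
  $z = \mathrm{lfc}\cdot\ln 2 / \sqrt{1/a' + 1/b' + 2\alpha}$ and
  two-sided normal p-values, BH-adjusted.  Peaks with zero counts in both
  cells are flagged and given `lfc = 0, p = 1`.

Classification thresholds default to q < 0.05 with |log2fc| > 2 for
specific sites and q > 0.1 with |log2fc| < 1 for shared sites; both are
arguments of `classify_peak()`, since tightening or relaxing them trades
the number of selected peaks against their quality.

# Numerical and convention choices

* **Coordinates** are 0-based half-open (BED) everywhere; conversion to
  the 1-based closed convention happens only at the Biostrings/IRanges
  boundary.
* **Read membership** is fragment-midpoint-in-peak (half-open), so each
  fragment counts for at most one of the disjoint merged peaks;
  `mode = "any"` switches to any-overlap counting.
* **Trimming** centers the 600 bp window on the interval midpoint; an odd
  remainder puts the extra base on the right; windows crossing a
  chromosome edge are shifted inward, preserving length.  A narrowPeak
  summit column can anchor the window instead (`use_summit = TRUE`).
* **PWM scores** are the plain sum of matrix entries over the one-hot
  window, on the forward sequence and its reverse complement; ambiguous
  bases contribute 0.  JASPAR matrices are used as stored (counts); an
  explicit log-odds transform (uniform background 0.25, pseudocount 0.01)
  is available because the score scale is a modeling choice, not part of
  the scanning contract.  Ties in top-k selections (top-3 motif scores,
  top-20 contact partners) break by scan position / genomic order, making
  every feature generator bit-deterministic.
* **Contact features** assign each peak to the 5 kb bin containing its
  midpoint; the peak's own bin is not a partner.  If fewer than k
  partners exist, the available ones are used rather than zero-padding
  (padding would drag min/mean toward zero and conflate sparsity with
  proximity); `pad_zero = TRUE` restores padding.  Distances are
  absolute differences of bin starts.
* **Difference features and channels** are cell A minus cell B
  throughout, stated in column/channel names.
* **Accessibility channels** are `asinh`-transformed per track and
  max-normalized to [0, 1] jointly over both cell types before the
  difference channel is formed (`scale_accessibility()`); the raw scale
  is available with `scale = FALSE`.
* **PRAUC** is computed as average precision with tied scores grouped, so
  a constant classifier scores the positive prevalence and a perfect one
  scores 1.  AUC is the normalized Mann–Whitney statistic with ties
  counted 1/2.

# The classifiers

**Boosted trees** (`train_xgboost()`, Rcpp backend): second-order
gradient boosting with exact greedy splits, L2 leaf regularization
(lambda = 1), logistic or softmax objective, maximum 1000 rounds with
validation early stopping (patience 50), and a 5 × 5 grid search over
depth {3, 5, 6, 7, 8} and learning rate {0.001, 0.1, 0.3, 0.5, 1}; the
final model is re-fit at the best grid point.  Trees are exported as node
tables, which makes the exact tree-SHAP computation (`tree_shap()`)
straightforward; its correctness is pinned by brute-force Shapley
enumeration over all feature coalitions on small ensembles.

**CNN** (`train_cnn()`, base-R/BLAS backend): three blocks of
convolution, ReLU, max-pool, dropout, then a dense/ReLU/dropout head and
a sigmoid (binary) or 3-unit softmax output.  The per-block
hyperparameters are open design choices; the defaults here are
(128 filters, kernel 15, pool 4, dropout 0.2), (256, 5, 4, 0.2),
(500, 3, 4, 0.2), hidden 64, head dropout 0.5 — the last block is fixed
at 500 filters so that `extract_cnn_features()` (global max over
positions of each last-conv filter, post-ReLU) yields exactly 500
sequence features.  Training: cross-entropy, Adam, batch size 300; a
warm-up phase trains a few epochs from several random initializations at
each learning rate in {0.01, 0.001, 0.0001}, the best
(initialization, rate) pair by validation loss is re-trained in full from
its stored initialization with early stopping, and the best-epoch weights
are kept.  Backpropagation is verified against finite differences in the
test suite; every stochastic step derives from an explicit seed through
named substreams, so runs are bit-reproducible.

**Attribution** (`attribute()`): per-position contributions relative to a
masking reference — the input with its sequence channels zeroed, or with
its chromatin channels zeroed.  The implementation backpropagates
multipliers with the rescale rule (exact for linear/conv layers and
ReLU); max-pooling routes each pooled delta to the input argmax (falling
back to the reference argmax when degenerate), which preserves the
completeness identity $\sum_i c_i = f(x) - f(\text{ref})$ exactly.  For
the three-class model the predicted class's margin is attributed.  The
contribution of the sigmoid/softmax *margin* (not the probability) is
reported, which is the standard choice for reference-based attribution.

# The synthetic world

`make_bundle()` emulates the full data model with planted ground truth:

* i.i.d. uniform ACGT genome over chr1 (1 Mb), chr8, chr16, chr18
  (0.6 Mb each).  chr1 is included because the fixed chromosome split
  sends chr8/16/18 entirely to test/validation — without an extra
  chromosome there would be no training data.
* 300 non-overlapping 600 bp peaks (100 per class), allocated to
  chromosomes proportionally to length, classes shuffled; each shared
  peak gets the motif consensus written at a random offset
  (`plant_motif = FALSE` removes all sequence signal — the
  "accessibility-only" world used by the CNN ablation tests).
* The first assay (accessibility/DNase) carries the class signal: a
  smooth central bump with multiplicative gamma noise, enriched
  `accessibility_effect`-fold (default 3) in the matching cell of
  specific peaks with independent realizations per cell, and one *common*
  realization in both cells for shared peaks — so shared peaks show high
  between-cell Pearson correlation and specific peaks do not, mirroring
  the real-data observation.  The other 14 assays are class-independent
  noise.
* Read counts are negative binomial (dispersion 0.05) with mean 160 for
  the bound cell and 160/8 for the unbound cell of a specific site
  (`count_fold_change = 8`, i.e. a planted |log2fc| of 3).
* Contacts decay exponentially with distance (rate 2e-5 per bp at 5 kb
  resolution) with a 2-fold enrichment in the matching cell of specific
  sites.

Setting every effect to 1 (and `plant_motif = FALSE`) removes all class
signal, which is the null world used to check that classifiers fall back
to chance.  What a green test establishes: that the pipeline recovers
*this* kind of planted, stationary, noise-free-mappability signal.  What
it does not establish: performance on real ChIP-seq data with GC bias,
copy-number variation, fragment-length structure, correlated assays or
realistic motif grammar — the generator makes no attempt at those, and
reproducing real-data performance numbers is out of scope here.

# Test-budget scale-downs

The full default CNN (128/256/500 filters) at the full 600 bp input is
deliberately not trained to convergence inside the test suite.  The
acceptance tests instead train 16/32/32-filter models (identical
architecture shape) with warm-up 3 inits × 8 epochs, at most 100 epochs,
patience 20, batch 100, on the default 300-peak bundle, which keeps the
whole suite within a single-CPU budget while leaving the planted effects
and seeds untouched.  Where the 500-dimensional feature extraction itself
is under test, the 500-filter last block is kept and only the early
blocks are narrowed, with a deliberately brief pre-training ("briefly
trained" is the contract; the feature dimension does not depend on fit
quality).  The warm-up budget matters: under-trained warm-ups can leave
the difference-channel model on the constant-prediction plateau, which is
why the acceptance runs use a longer warm-up than the minimal unit-test
settings.

# Known limitations

* The NB test uses one pooled dispersion and a normal Wald statistic; it
  is a documented stand-in, not a replacement for a mature
  differential-count package, and its q-values are slightly liberal under
  a pure null (lower-quartile dispersion).
* The gapped k-mer dimension depends on (l, k); the default
  (l = 6, k = 4, 3840 patterns) is a configuration choice, and other
  parameterizations change the feature count accordingly.
* `encode_cnn_all()` includes per-assay difference channels (49 channels
  total), mirroring the 7-channel accessibility design; a 34-channel
  variant without differences would be a reasonable alternative.
* The CNN backend is CPU-only base R; it is meant for desk-scale
  fixtures, not genome-scale training.
* Jaccard distances are base-pair-overlap based; a peak-count variant
  would differ for very unequal peak widths.
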