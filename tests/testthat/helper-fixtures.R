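# Shared fixtures built in code.  The small bundle is generated once per
# test run and cached; heavier, full-scale runs live in test-acceptance.R.

bs_test_cache <- new.env(parent = emptyenv())

# scaled-down fixture world for unit tests (same structure as the default)
small_config <- function(seed = 1L, ...) {
  fixture_config(seed = seed,
                 n_peaks = c(a_specific = 30L, b_specific = 30L,
                             shared = 30L),
                 chromosomes = c(chr1 = 300000L, chr8 = 150000L,
                                 chr16 = 150000L, chr18 = 150000L),
                 ...)
}

small_bundle <- function() {
  if (is.null(bs_test_cache$bundle))
    bs_test_cache$bundle <- make_bundle(small_config())
  bs_test_cache$bundle
}

write_temp_lines <- function(lines) {
  path <- tempfile()
  writeLines(lines, path)
  path
}

toy_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), seqs[[n]]))), path)
  path
}

# width-2 PWM used in scan tests: A scores 1 at pos 1, C scores 2 at pos 2
toy_pwm <- function() {
  m <- matrix(0, 4, 2, dimnames = list(c("A", "C", "G", "T"), NULL))
  m["A", 1] <- 1
  m["C", 2] <- 2
  pwm("toy", m)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# tiny CNN architecture for fast mechanical tests
tiny_spec <- function(n_out = 1L, last = 8L) {
  cnn_spec(blocks = list(
    list(filters = 4L, kernel = 5L, pool = 2L, dropout = 0),
    list(filters = last, kernel = 3L, pool = 2L, dropout = 0)),
    hidden = 8L, head_dropout = 0, n_out = n_out)
}

# reduced training budget used wherever a CNN must actually learn;
# documented scale-down of the default warm-up/epoch budget
fast_cnn_args <- function() {
  list(lr_grid = c(0.01, 0.001), warm_inits = 1L, warm_epochs = 2L,
       max_epochs = 25L, patience = 5L, batch_size = 100L)
}

# small CNN that still separates planted accessibility signal at 600 bp
ablation_spec <- function() {
  cnn_spec(blocks = list(
    list(filters = 16L, kernel = 15L, pool = 4L, dropout = 0.2),
    list(filters = 32L, kernel = 5L, pool = 4L, dropout = 0.2),
    list(filters = 32L, kernel = 3L, pool = 4L, dropout = 0.2)),
    hidden = 32L, n_out = 1L)
}

# encode a bundle's peaks for the CNN given a channel variant, using the
# first assay (DNase) tracks; returns list(x, y, split) for task B
encode_bundle_taskB <- function(bundle, variant = "plus") {
  cfg <- bundle$config
  peaks <- split_by_chromosome(bundle$truth)
  seqs <- extract_sequences(Biostrings::DNAStringSet(bundle$genome), peaks)
  assay <- cfg$assays[1]
  ta <- bundle$signals[[paste0(assay, "_A")]]
  tb <- bundle$signals[[paste0(assay, "_B")]]
  da <- lapply(seq_len(nrow(peaks)), function(i)
    signal_values(ta, peaks$chrom[i], peaks$start[i], peaks$end[i]))
  db <- lapply(seq_len(nrow(peaks)), function(i)
    signal_values(tb, peaks$chrom[i], peaks$start[i], peaks$end[i]))
  x <- encode_dataset(seqs, da, db, variant = variant)
  y <- as.integer(peaks$truth == "SHARED") # task B: shared = 1
  list(x = x, y = y, split = peaks$split, truth = peaks$truth)
}

# brute-force PWM scan oracle: score every window on both strands by
# explicit one-hot products
brute_scan <- function(seq, p) {
  score_at <- function(s, pos) {
    win <- substring(s, pos, pos + p$width - 1)
    sum(vapply(seq_len(p$width), function(j) {
      b <- substring(win, j, j)
      if (b %in% rownames(p$weights)) p$weights[b, j] else 0
    }, 0))
  }
  scan1 <- function(s)
    vapply(seq_len(nchar(s) - p$width + 1), function(i) score_at(s, i), 0)
  c(scan1(seq), scan1(reverse_complement(seq)))
}

# brute-force Shapley oracle over the cover-weighted expectation game
brute_shapley <- function(trees, x, M) {
  expv <- bindspec:::tree_expected_value
  v <- function(S) sum(vapply(trees, function(tr)
    expv(tr, x, seq_len(M) %in% S), 0))
  phi <- numeric(M)
  for (i in seq_len(M)) {
    rest <- setdiff(seq_len(M), i)
    for (k in 0:length(rest)) {
      combs <- if (k == 0) list(integer(0)) else
        asplit(utils::combn(rest, k), 2)
      for (S in combs)
        phi[i] <- phi[i] + factorial(k) * factorial(M - k - 1) /
          factorial(M) * (v(c(S, i)) - v(S))
    }
  }
  phi
}

# feature table (motif + chrom + hic) for a bundle's true peaks
bundle_features <- function(bundle) {
  peaks <- bundle$truth
  seqs <- extract_sequences(Biostrings::DNAStringSet(bundle$genome), peaks)
  mf <- motif_features(seqs, bundle$pwms)
  cf <- chromatin_features(peaks, bundle$signals)
  hf <- interaction_features(peaks, bundle$contacts$a, bundle$contacts$b)
  assemble_features(peaks, motif = mf, chrom = cf, hic = hf,
                    labels = peaks$truth)
}
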