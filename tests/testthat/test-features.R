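# Feature families: PWM scans, chromatin statistics, interaction
# statistics, gapped k-mers and assembly.

test_that("pwm_scan sums PWM entries over one-hot windows on both strands", {
  sc <- pwm_scan("AC", toy_pwm())
  expect_equal(sc[1], 3) # A at pos1 (1) + C at pos2 (2)

  set.seed(7)
  s <- random_dna(30)
  p <- pwm("r", matrix(rnorm(20), 4, 5))
  expect_equal(as.numeric(pwm_scan(s, p)), brute_scan(s, p))
  # both strands scanned: the score multiset is reverse-complement
  # invariant
  expect_equal(sort(as.numeric(pwm_scan(reverse_complement(s), p))),
               sort(as.numeric(pwm_scan(s, p))))
  expect_equal(as.numeric(pwm_scan(strrep("N", 10), p)), rep(0, 12))
  expect_error(pwm_scan("ACG", pwm("w", matrix(0, 4, 5))), "shorter")
})

test_that("motif_features stacks top-3 scores per PWM in panel order", {
  set.seed(8)
  pwms <- lapply(1:5, function(i) pwm(paste0("m", i), matrix(rnorm(8), 4, 2)))
  s <- random_dna(8)
  mf <- motif_features(s, pwms)
  expect_equal(ncol(mf), 15) # n x 3

  # exhaustive oracle: top-3 of all 14 window scores of a width-2 PWM
  all_scores <- brute_scan(s, pwms[[1]])
  expect_length(all_scores, 14)
  expect_equal(as.numeric(mf[1, 1:3]), sort(all_scores, decreasing = TRUE)[1:3])
  # descending order within each PWM block
  for (m in 1:5)
    expect_true(all(diff(as.numeric(mf[1, (3 * m - 2):(3 * m)])) <= 0))

  # a planted perfect match reaches the maximum attainable score
  p <- pwm("planted", matrix(c(0, 0, 0, 9, 9, 0, 0, 0), 4, 2)) # consensus TA
  planted <- paste0(random_dna(10, seed = 1), "TA", random_dna(10))
  expect_equal(max(motif_features(planted, list(p))[1, ]),
               sum(apply(p$weights, 2, max)))

  # invariant under reverse complement of the input
  expect_equal(motif_features(reverse_complement(s), pwms),
               motif_features(s, pwms), ignore_attr = TRUE)
})

test_that("chromatin_features emits 9 statistics per assay with A-B diffs", {
  b <- small_bundle()
  peaks <- b$truth[1:4, ]
  cf <- chromatin_features(peaks, b$signals)
  expect_equal(ncol(cf), 135) # 2 x 15 x 3 + 15 x 3
  expect_false(anyNA(cf))

  # min <= mean <= max within every (assay, cell) triple
  for (ai in seq_len(15)) {
    blk <- cf[, (6 * ai - 5):(6 * ai)]
    expect_true(all(blk[, 1] <= blk[, 2] & blk[, 2] <= blk[, 3]))
    expect_true(all(blk[, 4] <= blk[, 5] & blk[, 5] <= blk[, 6]))
  }

  # constant tracks give the constant and zero differences
  const <- list(
    signal_track(data.frame(chrom = "chr1", start = 0, end = 1000,
                            value = 2), "cellA", "DNase"),
    signal_track(data.frame(chrom = "chr1", start = 0, end = 1000,
                            value = 2), "cellB", "DNase"))
  one <- chromatin_features(genomic_intervals("chr1", 100, 700), const)
  expect_equal(as.numeric(one), c(rep(2, 6), 0, 0, 0))

  # brute-force per-base oracle on one random peak / track pair
  tr <- b$signals[["DNase_A"]]
  pk <- peaks[1, ]
  v <- signal_values(tr, pk$chrom, pk$start, pk$end)
  expect_length(v, 600)
  expect_equal(unname(cf[1, "DNase_cellA_min"]), min(v))
  expect_equal(unname(cf[1, "DNase_cellA_mean"]), mean(v))
  expect_equal(unname(cf[1, "DNase_cellA_max"]), max(v))

  expect_error(chromatin_features(peaks, b$signals[-1]), "missing signal")
})

test_that("interaction_features selects top-k partners like a full sort", {
  # single partner, k = 20: statistics collapse to that partner
  one <- contact_map(data.frame(chrom = "chr1", bin_i = 50000,
                                bin_j = 60000, count = 5))
  pk <- genomic_intervals("chr1", 50100, 50700)
  f <- interaction_features(pk, one, one)
  expect_equal(ncol(f), 18) # 2 x 6 + 6
  expect_equal(as.numeric(f[1, 1:6]), c(5, 5, 5, 10000, 10000, 10000))
  expect_equal(as.numeric(f[1, 13:18]), rep(0, 6)) # A - B differences

  # 40 random partners: top-20 selection equals the full-sort oracle
  set.seed(9)
  partners <- seq(0, 395000, by = 5000)
  partners <- setdiff(partners, 50000)[1:40]
  cnt <- round(runif(40, 0.1, 9), 3)
  cm <- contact_map(data.frame(chrom = "chr1",
                               bin_i = pmin(50000, partners),
                               bin_j = pmax(50000, partners), count = cnt))
  f <- interaction_features(pk, cm, cm, k = 20)
  top <- sort(cnt, decreasing = TRUE)[1:20]
  ord <- order(-cnt)[1:20]
  dst <- abs(partners[ord] - 50000)
  expect_equal(as.numeric(f[1, 1:6]),
               c(min(top), mean(top), max(top), min(dst), mean(dst),
                 max(dst)))

  # no contacts at the peak bin: zeros, flagged
  far <- genomic_intervals("chr1", 300000, 300600)
  f0 <- interaction_features(far, one, one)
  expect_equal(as.numeric(f0), rep(0, 18))
  expect_true(attr(f0, "no_contacts"))
  expect_error(interaction_features(pk, one,
                                    contact_map(one$entries, resolution = 1000)),
               "resolution")
})

test_that("gapped k-mer counts follow the combinatorial contract", {
  g <- gapped_kmer_features("AAAA", l = 2, k = 1, both_strands = FALSE)
  expect_equal(unname(g[1, "p1_A"]), 3L) # 3 windows, all A at position 1

  expect_equal(ncol(gapped_kmer_features("ACGTACGT", l = 4, k = 2)),
               choose(4, 2) * 16) # 96

  # counting identity: total matches = windows x choose(l, k) per strand
  set.seed(10)
  s <- random_dna(50)
  g <- gapped_kmer_features(s, l = 6, k = 4, both_strands = FALSE)
  expect_equal(sum(g), (50 - 6 + 1) * choose(6, 4))
  g2 <- gapped_kmer_features(s, l = 6, k = 4)
  expect_equal(sum(g2), 2 * (50 - 6 + 1) * choose(6, 4))

  expect_error(gapped_kmer_features("ACGT", l = 2, k = 3), "exceed")
})

test_that("assemble_features concatenates families with tags", {
  b <- small_bundle()
  peaks <- b$truth[1:3, ]
  seqs <- extract_sequences(Biostrings::DNAStringSet(b$genome), peaks)
  mf <- motif_features(seqs, b$pwms)
  cf <- chromatin_features(peaks, b$signals)
  hf <- interaction_features(peaks, b$contacts$a, b$contacts$b)
  ft <- assemble_features(peaks, motif = mf, chrom = cf, hf)
  expect_equal(ncol(ft$x), 15 + 135 + 18) # 168 with the 5-PWM panel
  expect_equal(as.vector(table(ft$families)[c("motif", "chrom", "hic")]),
               c(15L, 135L, 18L))

  sf <- gapped_kmer_features(seqs, l = 4, k = 2)
  with_seq <- assemble_features(peaks, motif = mf, chrom = cf, hic = hf,
                                seq = sf, include_seq = TRUE)
  expect_equal(ncol(with_seq$x), 168 + ncol(sf))

  expect_error(assemble_features(peaks, motif = mf[1:2, ], chrom = cf),
               "mismatch")
})

test_that("feature generators are deterministic", {
  b <- small_bundle()
  peaks <- b$truth[1:2, ]
  seqs <- extract_sequences(Biostrings::DNAStringSet(b$genome), peaks)
  expect_identical(motif_features(seqs, b$pwms), motif_features(seqs, b$pwms))
  expect_identical(chromatin_features(peaks, b$signals),
                   chromatin_features(peaks, b$signals))
  expect_identical(gapped_kmer_features(seqs, 5, 3),
                   gapped_kmer_features(seqs, 5, 3))
})
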