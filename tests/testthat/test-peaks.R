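# Differential peak selection: merging, counting, the NB test,
# classification thresholds, trimming and the chromosome split.

test_that("merge_peaks unions overlaps and leaves disjoint peaks alone", {
  a <- genomic_intervals("chr1", 100, 200)
  b <- genomic_intervals("chr1", 300, 400)
  m <- merge_peaks(a, b)
  expect_equal(m$start, c(100L, 300L))
  expect_equal(m$end, c(200L, 400L))

  # brute-force base-set oracle on a toy chromosome
  set.seed(11)
  for (rep in 1:5) {
    a <- genomic_intervals("chr1", s <- sample(0:400, 6), s + sample(10:80, 6))
    b <- genomic_intervals("chr1", s <- sample(0:400, 6), s + sample(10:80, 6))
    m <- merge_peaks(a, b)
    covered <- rep(FALSE, 600)
    for (df in list(a, b))
      for (i in seq_len(nrow(df)))
        covered[(df$start[i] + 1):df$end[i]] <- TRUE
    merged_covered <- rep(FALSE, 600)
    for (i in seq_len(nrow(m)))
      merged_covered[(m$start[i] + 1):m$end[i]] <- TRUE
    expect_identical(merged_covered, covered)
    if (nrow(m) > 1) expect_true(all(m$start[-1] >= m$end[-nrow(m)]))
  }
  expect_equal(nrow(merge_peaks(a[0, ], b[0, ])), 0L)
  expect_equal(merge_peaks(genomic_intervals("chr1", 100, 250),
                           genomic_intervals("chr1", 200, 400))$end, 400L)
})

test_that("count_reads uses half-open fragment-midpoint membership", {
  merged <- genomic_intervals("chr1", 100, 200)
  reads <- genomic_intervals("chr1", c(110, 140, 180), c(130, 160, 200))
  cc <- count_reads(merged, reads, reads[0, ])
  expect_equal(cc$count_a, 3L)
  expect_equal(cc$count_b, 0L)
  expect_equal(cc$length, 100L)

  # midpoint exactly at start counts, at end does not
  at_start <- genomic_intervals("chr1", 95, 105) # midpoint 100
  at_end <- genomic_intervals("chr1", 195, 205)  # midpoint 200
  expect_equal(count_reads(merged, at_start, at_start)$count_a, 1L)
  expect_equal(count_reads(merged, at_end, at_end)$count_a, 0L)

  # brute-force per-read membership oracle on a random toy set
  set.seed(5)
  m <- merge_peaks(genomic_intervals("chr1", c(0, 300, 700),
                                     c(150, 450, 900)),
                   genomic_intervals("chr2", c(50, 500), c(200, 640)))
  rs <- sample(0:900, 200, replace = TRUE)
  rd <- data.frame(chrom = sample(c("chr1", "chr2"), 200, replace = TRUE),
                   start = rs, end = rs + sample(20:60, 200, replace = TRUE))
  got <- count_reads(m, rd, rd[0, ])$count_a
  want <- vapply(seq_len(nrow(m)), function(i) {
    mid <- (rd$start + rd$end) %/% 2L
    sum(rd$chrom == m$chrom[i] & mid >= m$start[i] & mid < m$end[i])
  }, 0L)
  expect_equal(got, want)
})

test_that("normalize_count evaluates M / (N x L) x 1e9", {
  expect_equal(normalize_count(10, 1e6, 1000), 10)
  expect_equal(normalize_count(0, 1e6, 1000), 0)
  expect_equal(normalize_count(20, 2e6, 1000),
               normalize_count(10, 1e6, 1000))
  expect_error(normalize_count(1, 0, 10), "positive")
  expect_error(normalize_count(1, 10, 0), "positive")
})

test_that("differential_test is null-calibrated and recovers planted fold changes", {
  # identical counts: no effect, q near 1
  same <- data.frame(count_a = c(10, 50, 100, 7, 33),
                     count_b = c(10, 50, 100, 7, 33))
  res <- differential_test(same)
  expect_true(all(abs(res$log2fc) < 0.1))
  expect_true(all(res$qvalue > 0.99))

  # planted 8-fold increase (log2fc = 3) at n = 200, NB dispersion 0.05
  set.seed(1)
  n <- 200
  counted <- data.frame(count_a = rnbinom(n, mu = 50, size = 1 / 0.05),
                        count_b = rnbinom(n, mu = 400, size = 1 / 0.05))
  # the simulated libraries are depth-matched by construction, so the
  # global planted shift must not be absorbed by size factors
  res <- differential_test(counted, size_factors = "none")
  expect_lt(abs(median(res$log2fc) - 3), 0.3)

  # all-zero peaks are flagged with p = 1, log2fc = 0
  z <- differential_test(data.frame(count_a = c(0, 10), count_b = c(0, 90)))
  expect_true(z$all_zero[1])
  expect_equal(z$log2fc[1], 0)
  expect_equal(z$pvalue[1], 1)

  # BH q-values match a direct computation
  set.seed(2)
  counted <- data.frame(count_a = rnbinom(50, mu = 60, size = 10),
                        count_b = rnbinom(50, mu = 80, size = 10))
  res <- differential_test(counted)
  p <- res$pvalue
  m <- length(p)
  ord <- order(p)
  direct <- numeric(m)
  direct[ord] <- pmin(1, rev(cummin(rev(p[ord] * m / seq_len(m)))))
  expect_equal(res$qvalue, direct)
})

test_that("classify_peak applies the q-value / fold-change rules", {
  res <- data.frame(log2fc = c(-3, 0.5, 0, 3, -3, 0.5),
                    qvalue = c(0.01, 0.2, 0.07, 0.01, 0.2, 0.05))
  lab <- classify_peak(res)
  expect_equal(as.character(lab),
               c("A_SPECIFIC", "SHARED", "ABANDONED", "B_SPECIFIC",
                 "ABANDONED", "ABANDONED"))

  # swapping cell types + negating log2fc swaps the specific labels and
  # fixes SHARED / ABANDONED
  set.seed(3)
  rnd <- data.frame(log2fc = runif(300, -4, 4), qvalue = runif(300))
  lab <- as.character(classify_peak(rnd))
  swapped <- as.character(classify_peak(
    data.frame(log2fc = -rnd$log2fc, qvalue = rnd$qvalue)))
  map <- c(A_SPECIFIC = "B_SPECIFIC", B_SPECIFIC = "A_SPECIFIC",
           SHARED = "SHARED", ABANDONED = "ABANDONED")
  expect_identical(swapped, unname(map[lab]))
})

test_that("trim_peak yields exact-width midpoint windows", {
  expect_equal(trim_peak(genomic_intervals("chr1", 100, 1100))[, c("start", "end")],
               data.frame(start = 300L, end = 900L))
  expect_equal(trim_peak(genomic_intervals("chr1", 0, 600))$start, 0L)
  odd <- trim_peak(genomic_intervals("chr1", 0, 601))
  expect_equal(odd$end - odd$start, 600L)
  expect_equal(odd$start, 1L) # extra base goes to the right of the midpoint

  # extension of short peaks is symmetric
  short <- trim_peak(genomic_intervals("chr1", 1000, 1100)) # midpoint 1050
  expect_equal(short$start, 750L)
  expect_equal(short$end, 1350L)

  # boundary shift preserves length
  clipped <- trim_peak(genomic_intervals("chr1", 0, 100),
                       chrom_sizes = c(chr1 = 100000L))
  expect_equal(clipped$start, 0L)
  expect_equal(clipped$end, 600L)
  right <- trim_peak(genomic_intervals("chr1", 99900, 100000),
                     chrom_sizes = c(chr1 = 100000L))
  expect_equal(right$end, 100000L)
  expect_equal(right$end - right$start, 600L)
  expect_error(trim_peak(genomic_intervals("chr1", 0, 100),
                         chrom_sizes = c(chr1 = 500L)), "shorter than")
})

test_that("summit-anchored trimming is available behind a flag", {
  pk <- genomic_intervals("chr1", 1000, 2000)
  pk$summit <- 100L
  centered <- trim_peak(pk, use_summit = TRUE)
  expect_equal(centered$start, 800L)
  expect_equal(centered$end, 1400L)
})

test_that("split_by_chromosome implements the fixed chromosome split", {
  pk <- genomic_intervals(c("chr8", "chr16", "chr18", "chrY", "chr1", "chr2"),
                          rep(0, 6), rep(100, 6))
  sp <- split_by_chromosome(pk)
  expect_equal(as.character(sp$split),
               c("TEST", "TEST", "VAL", "EXCLUDED", "TRAIN", "TRAIN"))
  # exhaustive partition
  expect_false(any(is.na(sp$split)))
  expect_warning(split_by_chromosome(genomic_intervals("weird_contig", 0, 10)),
                 "unrecognized")
})

test_that("select_peaks labels every merged peak exactly once", {
  b <- small_bundle()
  sel <- select_peaks(b$peaks_a, b$peaks_b, b$reads$a, b$reads$b,
                      chrom_sizes = b$config$chromosomes)
  expect_true(all(sel$end - sel$start == 600L))
  expect_equal(sum(table(sel$label)), nrow(sel))
  expect_equal(sum(table(sel$split)), nrow(sel))
  expect_false(any(duplicated(sel$peak_id)))
})
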