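## Differential peak selection: merge peaks from two cell types, count
## reads, test for differential binding, classify into specific / shared /
## abandoned, trim to a fixed width and split by chromosome.

#' Merge peak calls from two cell types
#'
#' Overlapping or bookended-overlapping intervals are collapsed into their
#' union; the result is pairwise disjoint and sorted by (chrom, start).
#'
#' @param peaks_a,peaks_b Interval data frames (either may be empty).
#' @return Interval data frame of merged peaks.
#' @export
merge_peaks <- function(peaks_a, peaks_b) {
  all <- rbind(peaks_a[, c("chrom", "start", "end")],
               peaks_b[, c("chrom", "start", "end")])
  if (!nrow(all)) return(all)
  validate_intervals(all)
  parts <- split(all, all$chrom)
  out <- lapply(names(parts), function(ch) {
    # IRanges is 1-based closed; shift start by 1 on the way in and out
    ir <- IRanges::reduce(IRanges::IRanges(parts[[ch]]$start + 1L,
                                           parts[[ch]]$end))
    data.frame(chrom = ch, start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Count reads from two cell types falling into merged peaks
#'
#' By default a read is assigned to the peak containing its fragment
#' midpoint (`floor((start + end) / 2)`, half-open membership), so every
#' read is counted for at most one of the disjoint merged peaks.
#' `mode = "any"` counts a read for every peak it overlaps by >= 1 bp.
#'
#' @param merged Disjoint interval data frame (output of [merge_peaks()]).
#' @param reads_a,reads_b Read/fragment interval data frames per cell type.
#' @param mode Membership rule, `"midpoint"` (default) or `"any"`.
#' @return `merged` with integer columns `count_a`, `count_b` and `length`.
#' @export
count_reads <- function(merged, reads_a, reads_b,
                        mode = c("midpoint", "any")) {
  mode <- match.arg(mode)
  counts_one <- function(reads) {
    n <- integer(nrow(merged))
    if (!nrow(reads)) return(n)
    for (ch in unique(merged$chrom)) {
      pi <- which(merged$chrom == ch)
      rd <- reads[reads$chrom == ch, , drop = FALSE]
      if (!nrow(rd)) next
      p <- merged[pi, , drop = FALSE]
      if (mode == "midpoint") {
        mid <- (rd$start + rd$end) %/% 2L
        idx <- findInterval(mid, p$start)
        ok <- idx > 0L
        ok[ok] <- mid[ok] < p$end[idx[ok]]
        tab <- tabulate(idx[ok], nbins = nrow(p))
      } else {
        ir <- IRanges::IRanges(p$start + 1L, p$end)
        rr <- IRanges::IRanges(rd$start + 1L, rd$end)
        tab <- IRanges::countOverlaps(ir, rr)
      }
      n[pi] <- n[pi] + tab
    }
    n
  }
  merged$count_a <- counts_one(reads_a)
  merged$count_b <- counts_one(reads_b)
  merged$length <- merged$end - merged$start
  merged
}

#' Depth- and length-normalized read count
#'
#' `m / (n_total * len) * 1e9`: reads in the peak scaled by the total
#' mapped reads over all peaks and by peak length, so libraries of
#' different depth and peaks of different width are comparable.
#'
#' @param m Reads in the peak (vectorized).
#' @param n_total Total mapped reads over all peaks (> 0).
#' @param len Peak length in bp (> 0).
#' @return Normalized count(s).
#' @examples
#' normalize_count(10, 1e6, 1000) # 10
#' @export
normalize_count <- function(m, n_total, len) {
  if (any(n_total <= 0)) bs_stop("total read count must be positive")
  if (any(len <= 0)) bs_stop("peak length must be positive")
  m / (n_total * len) * 1e9
}

#' Negative-binomial Wald test for differential binding
#'
#' A self-contained stand-in for a full differential-count analysis: counts
#' are library-size normalized (sqrt ratio of totals), log2 fold-changes of
#' cell B over cell A use a pseudocount, a single dispersion shared across
#' peaks is estimated by a robust method of moments, and a Wald z-test with
#' the delta-method variance `1/mu + alpha` per condition gives p-values,
#' BH-adjusted to q-values.  Externally computed results can be supplied
#' instead via [read_differential_table()].
#'
#' @param counted Data frame with columns `count_a`, `count_b` (from
#'   [count_reads()]).
#' @param pseudocount Added to normalized counts before the log-ratio.
#' @param normalized Apply the depth/length normalization of
#'   [normalize_count()] to the counts first (mirrors the optional
#'   normalization step) instead of size-factor scaling.
#' @param size_factors `"median_ratio"` (default) rescales the two count
#'   vectors by the median per-peak ratio, robust against differential
#'   peaks; `"none"` compares raw counts (appropriate when libraries are
#'   known to be depth-matched, e.g. in simulations planting a global
#'   fold change).
#' @return Data frame with columns `log2fc`, `pvalue`, `qvalue`,
#'   `all_zero` (flag for peaks with no reads in either cell).
#' @export
differential_test <- function(counted, pseudocount = 1, normalized = FALSE,
                              size_factors = c("median_ratio", "none")) {
  size_factors <- match.arg(size_factors)
  if (nrow(counted) < 2) bs_stop("need at least 2 peaks for the test")
  ka <- as.numeric(counted$count_a)
  kb <- as.numeric(counted$count_b)
  if (any(ka < 0) || any(kb < 0)) bs_stop("negative counts")
  if (normalized) {
    len <- counted$end - counted$start
    a <- normalize_count(ka, max(sum(ka), 1), len)
    b <- normalize_count(kb, max(sum(kb), 1), len)
  } else if (size_factors == "median_ratio") {
    pos <- ka > 0 & kb > 0
    s <- if (any(pos)) sqrt(median(kb[pos] / ka[pos])) else 1
    a <- ka * s
    b <- kb / s
  } else {
    a <- ka
    b <- kb
  }
  mu <- (a + b) / 2
  # Pooled method-of-moments dispersion.  The A/B difference of a truly
  # differential peak inflates its moment estimate, so the lower quartile
  # across peaks is used: robust as long as < 75% of peaks are strongly
  # differential (slightly liberal under a pure null).
  v <- ((a - mu)^2 + (b - mu)^2)
  ok <- mu > 0
  alpha <- if (any(ok))
    max(0, quantile((v[ok] - mu[ok]) / mu[ok]^2, 0.25, names = FALSE)) else 0
  log2fc <- log2((b + pseudocount) / (a + pseudocount))
  se <- sqrt(1 / (a + pseudocount) + 1 / (b + pseudocount) + 2 * alpha) /
    log(2)
  z <- log2fc / se
  pvalue <- 2 * pnorm(-abs(z))
  zero <- ka == 0 & kb == 0
  log2fc[zero] <- 0
  pvalue[zero] <- 1
  data.frame(log2fc = log2fc, pvalue = pvalue,
             qvalue = p.adjust(pvalue, method = "BH"), all_zero = zero)
}

#' Load an externally computed differential-test table
#'
#' Accepts a TSV with columns `log2fc` (cell B over cell A), `pvalue`
#' and/or `qvalue` (e.g. exported from a dedicated differential-count
#' package); missing q-values are BH-computed from p-values.
#'
#' @param path TSV path with a header row.
#' @return Data frame with `log2fc`, `pvalue`, `qvalue`.
#' @export
read_differential_table <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  if (!"log2fc" %in% names(df)) bs_stop("column 'log2fc' missing in %s", path)
  if (!"qvalue" %in% names(df)) {
    if (!"pvalue" %in% names(df))
      bs_stop("need 'pvalue' or 'qvalue' in %s", path)
    df$qvalue <- p.adjust(df$pvalue, method = "BH")
  }
  if (!"pvalue" %in% names(df)) df$pvalue <- NA_real_
  df[, c("log2fc", "pvalue", "qvalue")]
}

#' Classify peaks into specific / shared / abandoned
#'
#' Default thresholds: q < 0.05 with log2 fold-change < -2 gives
#' `A_SPECIFIC` (cell A enriched), q < 0.05 with log2 fold-change > 2 gives
#' `B_SPECIFIC`, q > 0.1 with |log2 fold-change| < 1 gives `SHARED`;
#' everything else is `ABANDONED`.  Tightening or relaxing the thresholds
#' trades the number of selected peaks against their quality.
#'
#' @param result Data frame with `log2fc` and `qvalue` (B over A).
#' @param q_specific,lfc_specific Specific-site thresholds.
#' @param q_shared,lfc_shared Shared-site thresholds.
#' @return Factor with levels `A_SPECIFIC`, `B_SPECIFIC`, `SHARED`,
#'   `ABANDONED`.
#' @export
classify_peak <- function(result, q_specific = 0.05, lfc_specific = 2,
                          q_shared = 0.1, lfc_shared = 1) {
  lfc <- result$log2fc
  q <- result$qvalue
  label <- rep("ABANDONED", length(lfc))
  label[q < q_specific & lfc < -lfc_specific] <- "A_SPECIFIC"
  label[q < q_specific & lfc > lfc_specific] <- "B_SPECIFIC"
  label[q > q_shared & abs(lfc) < lfc_shared] <- "SHARED"
  factor(label, levels = c("A_SPECIFIC", "B_SPECIFIC", "SHARED", "ABANDONED"))
}

#' Trim peaks to a fixed length around their midpoints
#'
#' Each interval becomes exactly `target_len` bp, centered on its midpoint
#' (odd remainders put the extra base on the right); shorter intervals are
#' extended symmetrically.  When `use_summit = TRUE` and a `summit` column
#' is present, the window is centered on the summit instead.  Windows that
#' would cross a chromosome boundary are shifted inward to preserve length.
#'
#' @param intervals Interval data frame.
#' @param target_len Target width in bp (default 600).
#' @param chrom_sizes Optional named vector of chromosome lengths for
#'   boundary clipping.
#' @param use_summit Center on the narrowPeak summit when available?
#' @return Interval data frame with every width equal to `target_len`.
#' @export
trim_peak <- function(intervals, target_len = 600L, chrom_sizes = NULL,
                      use_summit = FALSE) {
  validate_intervals(intervals)
  if (target_len <= 0) bs_stop("target_len must be positive")
  center2 <- intervals$start + intervals$end # twice the midpoint
  if (use_summit && "summit" %in% names(intervals)) {
    s <- intervals$start + intervals$summit
    center2 <- ifelse(is.na(intervals$summit), center2, 2L * s)
  }
  new_start <- as.integer(ceiling((center2 - target_len) / 2))
  new_end <- new_start + as.integer(target_len)
  shift <- pmax(0L, -new_start) # left boundary
  if (!is.null(chrom_sizes)) {
    size <- chrom_sizes[intervals$chrom]
    if (any(is.na(size)))
      bs_stop("chromosome size missing for %s",
              intervals$chrom[which(is.na(size))[1]])
    if (any(size < target_len))
      bs_stop("chromosome shorter than target length %d", target_len)
    shift <- shift - pmax(0L, new_end + shift - as.integer(size))
  }
  out <- intervals
  out$start <- new_start + shift
  out$end <- new_end + shift
  if (any(out$start < 0)) bs_stop("cannot fit %d bp window", target_len)
  validate_intervals(out)
}

#' Assign train/validation/test splits by chromosome
#'
#' chr8 and chr16 form the test set, chr18 the validation set, chrY is
#' excluded, and every other chromosome goes to training — a
#' split-by-chromosome scheme that rules out positional overlap between
#' training and evaluation peaks.  Chromosome names are normalized to the
#' `chr` prefix first; names that do not look like chromosomes at all are
#' sent to TRAIN with a warning.
#'
#' @param peaks Interval data frame.
#' @param test,val,exclude Chromosome name vectors for each role.
#' @return `peaks` with a `split` factor column (`TRAIN`, `VAL`, `TEST`,
#'   `EXCLUDED`).
#' @export
split_by_chromosome <- function(peaks, test = c("chr8", "chr16"),
                                val = "chr18", exclude = "chrY") {
  chrom <- ifelse(grepl("^chr", peaks$chrom), peaks$chrom,
                  paste0("chr", peaks$chrom))
  unknown <- !grepl(.bs_chromosome_regex, chrom)
  if (any(unknown))
    warning(sprintf("unrecognized chromosome name(s) assigned to TRAIN: %s",
                    paste(unique(chrom[unknown]), collapse = ", ")),
            call. = FALSE)
  split <- rep("TRAIN", nrow(peaks))
  split[chrom %in% test] <- "TEST"
  split[chrom %in% val] <- "VAL"
  split[chrom %in% exclude] <- "EXCLUDED"
  peaks$split <- factor(split, levels = c("TRAIN", "VAL", "TEST", "EXCLUDED"))
  peaks
}

#' Full peak-selection pipeline
#'
#' Merge, count, test, classify, trim and split in one call.
#'
#' @param peaks_a,peaks_b Peak interval data frames for the two cell types.
#' @param reads_a,reads_b Read interval data frames.
#' @param differential Optional precomputed differential table (columns
#'   `log2fc`, `qvalue`) overriding the built-in test.
#' @param target_len Trimmed peak width (default 600 bp).
#' @param chrom_sizes Optional named chromosome lengths.
#' @param ... Passed to [classify_peak()].
#' @return Interval data frame with columns `label`, `split`, `log2fc`,
#'   `qvalue`, `count_a`, `count_b` and a `peak_id`.
#' @export
select_peaks <- function(peaks_a, peaks_b, reads_a, reads_b,
                         differential = NULL, target_len = 600L,
                         chrom_sizes = NULL, ...) {
  merged <- merge_peaks(peaks_a, peaks_b)
  counted <- count_reads(merged, reads_a, reads_b)
  res <- if (is.null(differential)) differential_test(counted) else differential
  counted$log2fc <- res$log2fc
  counted$qvalue <- res$qvalue
  counted$label <- classify_peak(res, ...)
  out <- trim_peak(counted, target_len, chrom_sizes)
  out <- split_by_chromosome(out)
  out$peak_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  out
}
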