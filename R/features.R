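## The four feature families computed per trimmed peak: motif scores from
## PWM scans, chromatin-landscape statistics, Hi-C contact statistics and
## gapped k-mer sequence counts.

# integer-encode a DNA string: A=1 C=2 G=3 T=4, anything else 5 (ambiguous)
dna_to_int <- function(seq) {
  v <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  v[is.na(v)] <- 5L
  v
}

#' Reverse complement of a DNA string
#' @param seq DNA string (ambiguous bases kept as N).
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

#' Scan a sequence with a PWM on both strands
#'
#' Each window of width w gets the score `sum_j weights[base_j, j]` — the
#' sum of the product of the PWM with the one-hot sequence matrix.  The
#' forward sequence and its reverse complement are both scanned; ambiguous
#' bases contribute 0 at their position.
#'
#' @param seq DNA string with `nchar(seq) >= pwm$width`.
#' @param pwm A `pwm` object.
#' @param both_strands Scan the reverse complement as well (default TRUE)?
#' @return Numeric vector of window scores, forward windows first, with a
#'   `strand` attribute; length `(L - w + 1)` per scanned strand.
#' @export
pwm_scan <- function(seq, pwm, both_strands = TRUE) {
  w <- pwm$width
  L <- nchar(seq)
  if (L < w)
    bs_stop("sequence length %d shorter than PWM width %d", L, w)
  weights5 <- rbind(pwm$weights, 0) # row 5: ambiguous base scores 0
  scan_one <- function(s) {
    b <- dna_to_int(s)
    n <- length(b) - w + 1L
    sc <- numeric(n)
    for (j in seq_len(w))
      sc <- sc + weights5[cbind(b[j:(j + n - 1L)], j)]
    sc
  }
  fwd <- scan_one(seq)
  if (!both_strands) {
    attr(fwd, "strand") <- rep("+", length(fwd))
    return(fwd)
  }
  rev <- scan_one(reverse_complement(seq))
  out <- c(fwd, rev)
  attr(out, "strand") <- rep(c("+", "-"), c(length(fwd), length(rev)))
  out
}

#' Top-3 PWM scores per motif as features
#'
#' For each PWM (in panel order) the three highest window scores over both
#' strands, descending, ties broken by scan position (leftmost, forward
#' strand first).  With n PWMs the vector has length 3n.
#'
#' @param seqs Character vector of DNA sequences (one per peak).
#' @param pwms List of `pwm` objects.
#' @return Matrix `length(seqs)` x `3 * length(pwms)` with columns
#'   `<id>_top1..3`.
#' @export
motif_features <- function(seqs, pwms) {
  stopifnot(length(pwms) >= 1)
  out <- matrix(0, length(seqs), 3L * length(pwms))
  colnames(out) <- as.vector(vapply(
    pwms, function(p) paste0(p$id, "_top", 1:3), character(3)))
  for (i in seq_along(seqs)) {
    for (m in seq_along(pwms)) {
      sc <- pwm_scan(seqs[i], pwms[[m]])
      if (length(sc) < 3)
        bs_stop("only %d scan windows for PWM %s; need >= 3",
                length(sc), pwms[[m]]$id)
      top <- sc[order(-sc)[1:3]] # stable order: leftmost wins ties
      out[i, (3L * (m - 1L) + 1L):(3L * m)] <- top
    }
  }
  out
}

#' Chromatin-landscape statistics per peak
#'
#' For every landscape assay and each of the two cell types, the minimum,
#' mean and maximum per-base signal across the peak; plus, per assay, the
#' cell A minus cell B difference of each statistic.  With 15 assays this
#' yields 2x15x3 + 15x3 = 135 features.
#'
#' @param peaks Interval data frame (trimmed, fixed-width peaks).
#' @param tracks List of `signal_track` objects covering every (assay,
#'   cell type) combination; the assay set must be identical in both cells.
#' @param cell_a,cell_b The two cell-type labels.
#' @return Matrix `nrow(peaks)` x `9 * n_assays`, columns named
#'   `chromstat_<assay>_<cell>_<stat>` then `chromstat_<assay>_diff_<stat>`.
#' @export
chromatin_features <- function(peaks, tracks, cell_a = "cellA",
                               cell_b = "cellB") {
  validate_intervals(peaks)
  key <- vapply(tracks, function(t) paste(t$cell_type, t$assay, sep = "/"), "")
  names(tracks) <- key
  assays <- unique(vapply(tracks, function(t) t$assay, ""))
  want <- c(outer(c(cell_a, cell_b), assays, paste, sep = "/"))
  missing <- setdiff(want, key)
  if (length(missing))
    bs_stop("missing signal track(s): %s", paste(missing, collapse = ", "))
  stats <- c("min", "mean", "max")
  n_assay <- length(assays)
  out <- matrix(0, nrow(peaks), 9L * n_assay)
  cn <- character(0)
  for (a in assays)
    for (cl in c(cell_a, cell_b))
      cn <- c(cn, paste(a, cl, stats, sep = "_"))
  for (a in assays) cn <- c(cn, paste(a, "diff", stats, sep = "_"))
  colnames(out) <- cn
  for (i in seq_len(nrow(peaks))) {
    for (ai in seq_len(n_assay)) {
      va <- signal_values(tracks[[paste(cell_a, assays[ai], sep = "/")]],
                          peaks$chrom[i], peaks$start[i], peaks$end[i])
      vb <- signal_values(tracks[[paste(cell_b, assays[ai], sep = "/")]],
                          peaks$chrom[i], peaks$start[i], peaks$end[i])
      sa <- c(min(va), mean(va), max(va))
      sb <- c(min(vb), mean(vb), max(vb))
      base <- 6L * (ai - 1L)
      out[i, (base + 1L):(base + 6L)] <- c(sa, sb)
      dbase <- 6L * n_assay + 3L * (ai - 1L)
      out[i, (dbase + 1L):(dbase + 3L)] <- sa - sb
    }
  }
  out
}

#' Hi-C interaction statistics per peak
#'
#' The peak is assigned to the contact-map bin containing its midpoint.
#' Per cell type, the `k` partner bins with the highest normalized contact
#' counts are selected (ties by genomic order, leftmost first; the peak's
#' own bin is not a partner) and the minimum, mean and maximum of their
#' counts and of their distances (|partner bin start - peak bin start|)
#' recorded; plus the cell A minus cell B differences of those six
#' statistics.  A peak whose bin has no contacts in a map gets six zeros
#' for that cell (flagged via the `no_contacts` attribute).  If fewer than
#' `k` partners exist, the available ones are used (set `pad_zero = TRUE`
#' to pad to `k` with zero-count, zero-distance entries instead).
#'
#' @param peaks Interval data frame.
#' @param contacts_a,contacts_b `contact_map` objects of equal resolution.
#' @param k Number of top interacting regions (default 20).
#' @param pad_zero Pad to `k` partners with zeros when fewer exist?
#' @return Matrix `nrow(peaks)` x 18.
#' @export
interaction_features <- function(peaks, contacts_a, contacts_b, k = 20L,
                                 pad_zero = FALSE) {
  validate_intervals(peaks)
  if (contacts_a$resolution != contacts_b$resolution)
    bs_stop("contact maps have different resolutions (%d vs %d)",
            contacts_a$resolution, contacts_b$resolution)
  res <- contacts_a$resolution
  stats6 <- function(map, chrom, bin) {
    p <- contact_partners(map, chrom, bin)
    if (!nrow(p)) return(list(v = numeric(6), empty = TRUE))
    ord <- order(-p$count, p$partner)[seq_len(min(k, nrow(p)))]
    cnt <- p$count[ord]
    dst <- abs(p$partner[ord] - bin)
    if (pad_zero && length(cnt) < k) {
      pad <- k - length(cnt)
      cnt <- c(cnt, numeric(pad))
      dst <- c(dst, numeric(pad))
    }
    list(v = c(min(cnt), mean(cnt), max(cnt), min(dst), mean(dst), max(dst)),
         empty = FALSE)
  }
  stats <- c("cnt_min", "cnt_mean", "cnt_max", "dist_min", "dist_mean",
             "dist_max")
  out <- matrix(0, nrow(peaks), 18L)
  colnames(out) <- c(paste0("A_", stats), paste0("B_", stats),
                     paste0("diff_", stats))
  empty <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    mid <- (peaks$start[i] + peaks$end[i]) %/% 2L
    bin <- (mid %/% res) * res
    sa <- stats6(contacts_a, peaks$chrom[i], bin)
    sb <- stats6(contacts_b, peaks$chrom[i], bin)
    out[i, ] <- c(sa$v, sb$v, sa$v - sb$v)
    empty[i] <- sa$empty || sb$empty
  }
  attr(out, "no_contacts") <- empty
  out
}

#' Gapped k-mer count features
#'
#' For every choice of `k` informative positions out of a word of length
#' `l` and every k-letter word over ACGT, the number of windows matching
#' that gapped pattern, summed over the forward strand and the reverse
#' complement.  The vector length is `choose(l, k) * 4^k`.  Windows whose
#' informative positions include an ambiguous base are skipped.
#'
#' @param seqs Character vector of DNA sequences.
#' @param l Word length (default 6).
#' @param k Number of informative positions (default 4); `k <= l`.
#' @param both_strands Add reverse-complement counts (default TRUE)?
#' @return Integer matrix `length(seqs)` x `choose(l, k) * 4^k`, columns
#'   named `p<positions>_<word>`.
#' @export
gapped_kmer_features <- function(seqs, l = 6L, k = 4L, both_strands = TRUE) {
  if (k > l) bs_stop("k (%d) must not exceed l (%d)", k, l)
  combos <- utils::combn(l, k)
  n_words <- 4L^k
  n_feat <- ncol(combos) * n_words
  bases <- c("A", "C", "G", "T")
  words <- vapply(0:(n_words - 1L), function(i) {
    d <- integer(k)
    for (m in k:1) { d[m] <- i %% 4L; i <- i %/% 4L }
    paste(bases[d + 1L], collapse = "")
  }, "")
  cn <- character(n_feat)
  for (ci in seq_len(ncol(combos)))
    cn[((ci - 1L) * n_words + 1L):(ci * n_words)] <-
      paste0("p", paste(combos[, ci], collapse = "."), "_", words)
  count_strand <- function(b) {
    n_win <- length(b) - l + 1L
    cnt <- integer(n_feat)
    if (n_win < 1L) return(cnt)
    pow <- 4L^((k - 1L):0)
    for (ci in seq_len(ncol(combos))) {
      idx <- integer(n_win)
      ok <- rep(TRUE, n_win)
      for (m in seq_len(k)) {
        bm <- b[combos[m, ci] + 0:(n_win - 1L)]
        ok <- ok & bm <= 4L
        idx <- idx + (pmin(bm, 4L) - 1L) * pow[m]
      }
      tab <- tabulate(idx[ok] + 1L, nbins = n_words)
      cnt[((ci - 1L) * n_words + 1L):(ci * n_words)] <-
        cnt[((ci - 1L) * n_words + 1L):(ci * n_words)] + tab
    }
    cnt
  }
  out <- matrix(0L, length(seqs), n_feat)
  colnames(out) <- cn
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) < l)
      bs_stop("sequence %d shorter than word length %d", i, l)
    cnt <- count_strand(dna_to_int(seqs[i]))
    if (both_strands)
      cnt <- cnt + count_strand(dna_to_int(reverse_complement(seqs[i])))
    out[i, ] <- cnt
  }
  out
}

#' Construct a feature table
#'
#' A matrix of named real-valued features with a family tag (`seq`,
#' `motif`, `chrom`, `hic`) per column and an optional label per row.
#'
#' @param x Numeric matrix, peaks x features, unique column names, no
#'   missing values.
#' @param families Character vector of family tags, one per column.
#' @param labels Optional per-row task labels.
#' @return Object of class `feature_table` with elements `x`, `families`,
#'   `labels`.
#' @export
feature_table <- function(x, families, labels = NULL) {
  stopifnot(is.matrix(x), length(families) == ncol(x))
  if (anyNA(x)) bs_stop("feature table contains missing values")
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    bs_stop("feature columns must have unique names")
  bad <- setdiff(unique(families), c("seq", "motif", "chrom", "hic"))
  if (length(bad))
    bs_stop("unknown feature family: %s", paste(bad, collapse = ", "))
  if (!is.null(labels) && length(labels) != nrow(x))
    bs_stop("labels length (%d) != number of rows (%d)", length(labels),
            nrow(x))
  if (is.null(rownames(x))) rownames(x) <- paste0("peak", seq_len(nrow(x)))
  structure(list(x = x, families = families, labels = labels),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table: %d peaks x %d features (%s)>\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s:%d", names(table(x$families)),
                            table(x$families)), collapse = ", ")))
  invisible(x)
}

#' Concatenate per-family feature matrices into one table
#'
#' Column-wise concatenation with family tags.  The default configuration
#' for the tree model excludes the `seq` family (ablations show sequence
#' features add little once motif/chromatin/interaction features are
#' present); pass `include_seq = TRUE` to keep it.
#'
#' @param peaks Interval data frame with a `peak_id` column (row ids).
#' @param motif,chrom,hic,seq Numeric matrices with `nrow(peaks)` rows
#'   (any may be NULL).
#' @param labels Optional per-peak labels.
#' @param include_seq Include the `seq` family when given?
#' @return A `feature_table`.
#' @export
assemble_features <- function(peaks, motif = NULL, chrom = NULL, hic = NULL,
                              seq = NULL, labels = NULL,
                              include_seq = FALSE) {
  parts <- list(motif = motif, chrom = chrom, hic = hic)
  if (include_seq) parts$seq <- seq
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (!length(parts)) bs_stop("no feature families given")
  nr <- vapply(parts, nrow, 0L)
  if (length(unique(c(nr, nrow(peaks)))) != 1L)
    bs_stop("row-count mismatch between feature families (%s) and peaks (%d)",
            paste(nr, collapse = ", "), nrow(peaks))
  x <- do.call(cbind, unname(parts))
  families <- rep(names(parts), vapply(parts, ncol, 0L))
  rownames(x) <- if ("peak_id" %in% names(peaks)) peaks$peak_id else NULL
  feature_table(x, families, labels)
}
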