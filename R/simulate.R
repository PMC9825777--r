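## Synthetic fixture generator: a random genome, planted cell-type-
## specific / shared peaks, accessibility tracks, negative-binomial read
## counts and distance-decaying contact maps, with known ground truth, so
## the whole pipeline runs without external data.

.bs_default_assays <- c("DNase", "H2AZ", "H3K4me1", "H3K4me2", "H3K4me3",
                        "H3K9ac", "H3K9me3", "H3K27ac", "H3K27me3",
                        "H3K36me3", "H3K79me2", "H4K20me1", "MNase",
                        "RNAseq", "Methyl")

#' Default planted motif (a strong 10 bp count PWM)
#' @return A `pwm` object.
#' @export
default_motif <- function() {
  consensus <- c("T", "G", "A", "C", "G", "T", "C", "A", "T", "C")
  m <- matrix(5, 4, length(consensus), dimnames = list(c("A", "C", "G", "T"),
                                                       NULL))
  m[cbind(match(consensus, rownames(m)), seq_along(consensus))] <- 85
  pwm("planted_motif", m)
}

#' Configuration of the synthetic fixture generator
#'
#' Defaults describe the emulated world: 600 bp peaks in three planted
#' classes on a few ~0.6-1 Mb chromosomes (including chr8/chr16/chr18 so
#' the chromosome split is exercised, plus chr1 so a training split
#' exists), a motif planted in shared sites, a 3-fold accessibility
#' enrichment in the matching cell type of specific sites, 8-fold
#' ChIP-read enrichment with negative-binomial noise (dispersion 0.05),
#' and exponentially distance-decaying Hi-C contacts at 5 kb resolution.
#'
#' @param seed Master integer seed; every stage derives a named substream.
#' @param n_peaks Named integer vector: peaks per class (`a_specific`,
#'   `b_specific`, `shared`).
#' @param chromosomes Named integer vector of chromosome lengths in bp.
#' @param peak_width Peak width (default 600 bp).
#' @param motif `pwm` planted in shared sites; `plant_motif = FALSE`
#'   disables planting.
#' @param plant_motif Plant the motif consensus in shared peaks?
#' @param accessibility_effect Multiplicative accessibility enrichment in
#'   the matching cell type of specific sites (> 1 for a planted effect;
#'   1 removes the signal).
#' @param count_fold_change Expected ChIP read-count fold change between
#'   bound and unbound cell for specific sites.
#' @param count_base_mean Mean read count of a bound peak.
#' @param nb_dispersion Negative-binomial dispersion of read counts.
#' @param contact_decay Exponential distance-decay rate of contacts, per
#'   bp.
#' @param contact_effect Contact enrichment in the matching cell type of
#'   specific sites.
#' @param assays Landscape assay names (15 by default; the first is
#'   treated as the accessibility/DNase track).
#' @param resolution Contact-map bin width (default 5000 bp).
#' @param signal_bin Signal track bin width in bp (default 10).
#' @param read_length Simulated fragment length (default 100 bp).
#' @return `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L,
                           n_peaks = c(a_specific = 100L, b_specific = 100L,
                                       shared = 100L),
                           chromosomes = c(chr1 = 1000000L, chr8 = 600000L,
                                           chr16 = 600000L, chr18 = 600000L),
                           peak_width = 600L, motif = default_motif(),
                           plant_motif = TRUE, accessibility_effect = 3,
                           count_fold_change = 8, count_base_mean = 160,
                           nb_dispersion = 0.05, contact_decay = 2e-5,
                           contact_effect = 2,
                           assays = .bs_default_assays,
                           resolution = 5000L, signal_bin = 10L,
                           read_length = 100L) {
  stopifnot(all(n_peaks >= 0), all(chromosomes > 0), peak_width > 0,
            nb_dispersion > 0, contact_decay > 0, resolution > 0)
  if (accessibility_effect < 1 || count_fold_change < 1 ||
      contact_effect < 1)
    bs_stop("planted effect sizes must be >= 1")
  structure(as.list(environment()), class = "fixture_config")
}

#' Generate a random genome
#'
#' I.i.d. uniform A/C/G/T per chromosome, reproducible from the seed.
#'
#' @param config A [fixture_config()].
#' @return Named character vector of chromosome sequences.
#' @export
make_genome <- function(config) {
  set.seed(bs_child_seed(config$seed, "genome"))
  vapply(names(config$chromosomes), function(ch)
    paste(sample(c("A", "C", "G", "T"), config$chromosomes[[ch]],
                 replace = TRUE), collapse = ""),
    "")
}

#' Place labeled peaks and plant the motif
#'
#' Non-overlapping fixed-width peaks distributed over chromosomes
#' proportionally to length, with shuffled ground-truth class labels; the
#' motif consensus is written into the genome at a random offset inside
#' every shared peak.
#'
#' @param config A [fixture_config()].
#' @param genome Output of [make_genome()].
#' @return List with `peaks` (interval data frame with `truth` and
#'   `peak_id`) and the possibly modified `genome`.
#' @export
make_peaks <- function(config, genome) {
  set.seed(bs_child_seed(config$seed, "peaks"))
  n_tot <- sum(config$n_peaks)
  sizes <- config$chromosomes
  alloc <- round(n_tot * sizes / sum(sizes))
  alloc[alloc < 1] <- 1L
  while (sum(alloc) > n_tot) alloc[which.max(alloc)] <-
      alloc[which.max(alloc)] - 1L
  while (sum(alloc) < n_tot) alloc[which.min(alloc)] <-
      alloc[which.min(alloc)] + 1L
  peaks <- list()
  margin <- 5000L
  for (ch in names(sizes)) {
    n_i <- alloc[[ch]]
    if (n_i == 0L) next
    usable <- sizes[[ch]] - 2L * margin
    step <- usable %/% n_i
    if (step < config$peak_width + 200L)
      bs_stop("chromosome %s too small for %d peaks", ch, n_i)
    jit <- sample.int(min(step - config$peak_width, 200L), n_i,
                      replace = TRUE)
    start <- margin + (seq_len(n_i) - 1L) * step + jit
    peaks[[ch]] <- data.frame(chrom = ch, start = as.integer(start),
                              end = as.integer(start + config$peak_width),
                              stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, peaks)
  rownames(peaks) <- NULL
  truth <- sample(rep(c("A_SPECIFIC", "B_SPECIFIC", "SHARED"),
                      config$n_peaks[c("a_specific", "b_specific",
                                       "shared")]))
  peaks$truth <- truth
  peaks$peak_id <- sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)
  if (config$plant_motif) {
    cons <- paste(rownames(config$motif$weights)[
      apply(config$motif$weights, 2, which.max)], collapse = "")
    w <- nchar(cons)
    for (i in which(peaks$truth == "SHARED")) {
      off <- sample.int(config$peak_width - w, 1L)
      at <- peaks$start[i] + off # 0-based; substr is 1-based
      substr(genome[[peaks$chrom[i]]], at + 1L, at + w) <- cons
    }
  }
  list(peaks = peaks, genome = genome)
}

# one simulated accessibility-style profile over the peak bins: a smooth
# central bump with multiplicative gamma noise
bs_bump_profile <- function(n_bins, amplitude) {
  center <- n_bins / 2
  shape <- exp(-((seq_len(n_bins) - center)^2) / (2 * (n_bins / 6)^2))
  amplitude * shape * rgamma(n_bins, shape = 8, rate = 8)
}

#' Simulate signal tracks, reads and contact maps for labeled peaks
#'
#' The first assay carries the planted accessibility signal: specific
#' peaks are enriched `accessibility_effect`-fold in the matching cell
#' type only (independent realizations between cells, so the between-cell
#' correlation is low), shared peaks get one common realized profile in
#' both cells (high correlation).  Remaining assays are class-independent
#' noise.  Read counts are negative-binomial with the class-consistent
#' fold change; contacts decay exponentially with distance with a
#' contact enrichment in the matching cell type.
#'
#' @param config A [fixture_config()].
#' @param peaks Peak data frame from [make_peaks()].
#' @return List with `signals` (list of `signal_track`, one per assay and
#'   cell type), `reads` (list `a`, `b` of read interval data frames) and
#'   `contacts` (list `a`, `b` of `contact_map`).
#' @export
make_signals_counts_contacts <- function(config, peaks) {
  n_bins <- config$peak_width %/% config$signal_bin
  bin0 <- function(i) peaks$start[i] + (seq_len(n_bins) - 1L) *
    config$signal_bin
  baseline <- 0.5
  amp <- 2
  eff <- config$accessibility_effect

  set.seed(bs_child_seed(config$seed, "signals"))
  signals <- list()
  for (assay in config$assays) {
    is_dnase <- assay == config$assays[1]
    rec_a <- rec_b <- vector("list", nrow(peaks))
    for (i in seq_len(nrow(peaks))) {
      noise_a <- baseline * rgamma(n_bins, shape = 6, rate = 6)
      noise_b <- baseline * rgamma(n_bins, shape = 6, rate = 6)
      if (is_dnase) {
        common <- bs_bump_profile(n_bins, amp)
        va <- switch(peaks$truth[i],
                     A_SPECIFIC = noise_a + eff * bs_bump_profile(n_bins, amp),
                     B_SPECIFIC = noise_a + bs_bump_profile(n_bins, amp),
                     SHARED = noise_a + common)
        vb <- switch(peaks$truth[i],
                     A_SPECIFIC = noise_b + bs_bump_profile(n_bins, amp),
                     B_SPECIFIC = noise_b + eff * bs_bump_profile(n_bins, amp),
                     SHARED = noise_b + common)
      } else {
        va <- noise_a + bs_bump_profile(n_bins, 1)
        vb <- noise_b + bs_bump_profile(n_bins, 1)
      }
      s0 <- bin0(i)
      rec_a[[i]] <- data.frame(chrom = peaks$chrom[i], start = s0,
                               end = s0 + config$signal_bin, value = va)
      rec_b[[i]] <- data.frame(chrom = peaks$chrom[i], start = s0,
                               end = s0 + config$signal_bin, value = vb)
    }
    signals[[paste0(assay, "_A")]] <-
      signal_track(do.call(rbind, rec_a), "cellA", assay)
    signals[[paste0(assay, "_B")]] <-
      signal_track(do.call(rbind, rec_b), "cellB", assay)
  }

  set.seed(bs_child_seed(config$seed, "reads"))
  mu_bound <- config$count_base_mean
  mu_unbound <- mu_bound / config$count_fold_change
  size <- 1 / config$nb_dispersion
  draw_reads <- function(cell) {
    out <- vector("list", nrow(peaks))
    for (i in seq_len(nrow(peaks))) {
      mu <- switch(peaks$truth[i],
                   A_SPECIFIC = if (cell == "a") mu_bound else mu_unbound,
                   B_SPECIFIC = if (cell == "b") mu_bound else mu_unbound,
                   SHARED = mu_bound)
      n <- rnbinom(1, mu = mu, size = size)
      if (n == 0) next
      s <- peaks$start[i] +
        sample.int(config$peak_width - config$read_length, n, replace = TRUE)
      out[[i]] <- data.frame(chrom = peaks$chrom[i], start = s,
                             end = s + config$read_length)
    }
    do.call(rbind, out[!vapply(out, is.null, TRUE)])
  }
  reads <- list(a = draw_reads("a"), b = draw_reads("b"))

  set.seed(bs_child_seed(config$seed, "contacts"))
  res <- config$resolution
  draw_contacts <- function(cell) {
    rows <- list()
    for (i in seq_len(nrow(peaks))) {
      mid <- (peaks$start[i] + peaks$end[i]) %/% 2L
      bin <- (mid %/% res) * res
      enr <- switch(peaks$truth[i],
                    A_SPECIFIC = if (cell == "a") config$contact_effect else 1,
                    B_SPECIFIC = if (cell == "b") config$contact_effect else 1,
                    SHARED = sqrt(config$contact_effect))
      offs <- setdiff(-25:25, 0)
      offs <- offs[runif(length(offs)) < 0.6]
      partner <- bin + offs * res
      ok <- partner >= 0 & partner + res <=
        config$chromosomes[[peaks$chrom[i]]]
      partner <- partner[ok]
      if (!length(partner)) next
      cnt <- 10 * enr * exp(-config$contact_decay * abs(partner - bin)) *
        rgamma(length(partner), shape = 10, rate = 10)
      lo <- pmin(bin, partner)
      hi <- pmax(bin, partner)
      rows[[i]] <- data.frame(chrom = peaks$chrom[i], bin_i = lo,
                              bin_j = hi, count = round(cnt, 4))
    }
    df <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    df <- df[!duplicated(df[, c("chrom", "bin_i", "bin_j")]), ]
    contact_map(df, resolution = res,
                cell_type = if (cell == "a") "cellA" else "cellB")
  }
  contacts <- list(a = draw_contacts("a"), b = draw_contacts("b"))
  list(signals = signals, reads = reads, contacts = contacts)
}

#' Generate a complete synthetic bundle in memory
#'
#' Runs [make_genome()], [make_peaks()] and
#' [make_signals_counts_contacts()], derives per-cell peak-call files
#' (specific + shared peaks of each cell, boundary-jittered) and a small
#' PWM panel (the planted motif plus decoys).
#'
#' @param config A [fixture_config()].
#' @return Object of class `bs_bundle` with elements `config`, `genome`,
#'   `truth`, `peaks_a`, `peaks_b`, `reads`, `signals`, `contacts`,
#'   `pwms`.
#' @export
make_bundle <- function(config = fixture_config()) {
  genome <- make_genome(config)
  pk <- make_peaks(config, genome)
  sim <- make_signals_counts_contacts(config, pk$peaks)
  set.seed(bs_child_seed(config$seed, "calls"))
  jitter_calls <- function(df) {
    j1 <- sample.int(51L, nrow(df), replace = TRUE) - 26L
    j2 <- sample.int(51L, nrow(df), replace = TRUE) - 26L
    data.frame(chrom = df$chrom, start = pmax(0L, df$start + j1),
               end = df$end + j2, stringsAsFactors = FALSE)
  }
  truth <- pk$peaks
  peaks_a <- jitter_calls(truth[truth$truth %in% c("A_SPECIFIC", "SHARED"), ])
  peaks_b <- jitter_calls(truth[truth$truth %in% c("B_SPECIFIC", "SHARED"), ])
  set.seed(bs_child_seed(config$seed, "decoys"))
  decoys <- lapply(1:4, function(d) {
    m <- matrix(rgamma(40, shape = 2, rate = 1) * 10, 4, 10)
    pwm(paste0("decoy", d), round(m, 2))
  })
  structure(list(config = config, genome = pk$genome, truth = truth,
                 peaks_a = peaks_a, peaks_b = peaks_b, reads = sim$reads,
                 signals = sim$signals, contacts = sim$contacts,
                 pwms = c(list(config$motif), decoys)),
            class = "bs_bundle")
}

#' @export
print.bs_bundle <- function(x, ...) {
  cat(sprintf("<bs_bundle: %d peaks on %d chromosomes, %d signal tracks>\n",
              nrow(x$truth), length(x$genome), length(x$signals)))
  invisible(x)
}

#' Write a bundle to standard-format files
#'
#' Emits FASTA, per-cell peak BEDs, per-cell read BEDs, one bedGraph per
#' (assay, cell type), two contact triplet files, a JASPAR PWM panel and a
#' ground-truth TSV.  The directory loads back through the package's
#' readers unmodified; the same seed gives a byte-identical bundle.
#'
#' @param bundle Output of [make_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      bs_stop("cannot create directory %s", dir)
  fa <- Biostrings::DNAStringSet(bundle$genome)
  Biostrings::writeXStringSet(fa, file.path(dir, "genome.fa"))
  write_bed(bundle$peaks_a, file.path(dir, "peaks_cellA.bed"))
  write_bed(bundle$peaks_b, file.path(dir, "peaks_cellB.bed"))
  write_bed(bundle$reads$a, file.path(dir, "reads_cellA.bed"))
  write_bed(bundle$reads$b, file.path(dir, "reads_cellB.bed"))
  sigdir <- file.path(dir, "signals")
  dir.create(sigdir, showWarnings = FALSE)
  manifest <- list()
  for (nm in names(bundle$signals)) {
    tr <- bundle$signals[[nm]]
    path <- file.path(sigdir, paste0(nm, ".bedGraph"))
    recs <- do.call(rbind, lapply(names(tr$data), function(ch)
      data.frame(chrom = ch, tr$data[[ch]])))
    data.table::fwrite(recs, path, sep = "\t", col.names = FALSE)
    manifest[[length(manifest) + 1L]] <-
      data.frame(assay = tr$assay, cell_type = tr$cell_type,
                 path = file.path("signals", basename(path)))
  }
  data.table::fwrite(do.call(rbind, manifest),
                     file.path(dir, "signal_manifest.tsv"), sep = "\t")
  for (cell in c("a", "b"))
    data.table::fwrite(as.data.frame(bundle$contacts[[cell]]$entries),
                       file.path(dir, sprintf("contacts_cell%s.txt",
                                              toupper(cell))),
                       sep = "\t", col.names = FALSE)
  jaspar <- unlist(lapply(bundle$pwms, function(p) c(
    paste0(">", p$id),
    vapply(rownames(p$weights), function(b)
      sprintf("%s [ %s ]", b, paste(format(p$weights[b, ], trim = TRUE),
                                    collapse = " ")), ""))))
  writeLines(jaspar, file.path(dir, "pwms.jaspar"))
  data.table::fwrite(bundle$truth, file.path(dir, "truth.tsv"), sep = "\t")
  invisible(dir)
}
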