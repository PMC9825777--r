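## Readers and writers for the external formats the pipeline touches.
## All interval arithmetic in this package is 0-based half-open (BED
## convention); FASTA access through Biostrings converts at the boundary.

#' Construct a set of genomic intervals
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`
#' (0-based half-open) and optionally `strand`; extra columns are carried
#' along untouched.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; `start` is 0-based inclusive, `end`
#'   0-based exclusive, so `end - start` is the width in bp.
#' @param strand Strand, one of `"+"`, `"-"`, `"."` (recycled).
#' @return A validated data frame of intervals.
#' @examples
#' genomic_intervals("chr1", 100, 700)
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
}

#' Validate an interval data frame
#'
#' Checks the 0-based half-open invariants: non-empty chromosome names and
#' `end > start` for every row.
#'
#' @param df Data frame with columns `chrom`, `start`, `end`.
#' @return `df`, invisibly unchanged, or an error.
#' @export
validate_intervals <- function(df) {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  bad <- which(!nzchar(df$chrom) | is.na(df$chrom))
  if (length(bad)) bs_stop("empty chromosome name at row %d", bad[1])
  bad <- which(!(df$end > df$start))
  if (length(bad))
    bs_stop("interval end <= start at row %d (%s:%d-%d)", bad[1],
            df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]])
  df
}

#' Read peak calls from a BED or narrowPeak file
#'
#' Coordinates are kept verbatim in the file's 0-based half-open
#' convention.  For narrowPeak input, the summit offset (column 10) is
#' attached as a `summit` column when present; a value of -1 becomes `NA`.
#'
#' @param path Path to a tab-separated BED3+ or narrowPeak file.
#' @param dialect `"BED"` or `"narrowPeak"`.
#' @return Data frame of intervals in file order.
#' @export
read_peaks <- function(path, dialect = c("BED", "narrowPeak")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) bs_stop("peak file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(genomic_intervals(character(), integer(), integer())[0, ])
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3))
    bs_stop("malformed line %d: fewer than 3 tab-separated columns",
            which(ncol < 3)[1])
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) bs_stop("malformed line %d: non-integer coordinate", bad[1])
  bad <- which(end <= start)
  if (length(bad))
    bs_stop("invalid interval at line %d: end (%d) <= start (%d)",
            bad[1], end[bad[1]], start[bad[1]])
  df <- data.frame(chrom = chrom, start = start, end = end,
                   strand = ".", stringsAsFactors = FALSE)
  if (dialect == "narrowPeak" && all(ncol >= 10)) {
    smt <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 10L)))
    smt[!is.na(smt) & smt < 0] <- NA_integer_
    df$summit <- smt
    strand <- vapply(fields, `[[`, "", 6L)
    df$strand <- ifelse(strand %in% c("+", "-"), strand, ".")
  }
  validate_intervals(df)
}

#' Write intervals as BED
#'
#' Emits chrom/start/end plus any extra columns, tab-separated, no header.
#' The first three columns round-trip byte-identically through
#' [read_peaks()].
#'
#' @param df Interval data frame.
#' @param path Output path.
#' @param extra_cols Character vector of additional columns to write.
#' @export
write_bed <- function(df, path, extra_cols = character()) {
  validate_intervals(df)
  out <- df[, c("chrom", "start", "end", intersect(extra_cols, names(df)))]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract uppercase DNA sequences for intervals
#'
#' @param genome FASTA path or a [Biostrings::DNAStringSet].
#' @param intervals Interval data frame.
#' @return Character vector of uppercase sequences, one per interval, each
#'   of length `end - start`.
#' @export
extract_sequences <- function(genome, intervals) {
  validate_intervals(intervals)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  nm <- sub("\\s.*$", "", names(genome))
  idx <- match(intervals$chrom, nm)
  if (anyNA(idx))
    bs_stop("chromosome(s) missing from FASTA: %s",
            paste(unique(intervals$chrom[is.na(idx)]), collapse = ", "))
  len <- Biostrings::width(genome)[idx]
  bad <- which(intervals$start < 0 | intervals$end > len)
  if (length(bad))
    bs_stop("interval out of chromosome bounds at row %d (%s:%d-%d, length %d)",
            bad[1], intervals$chrom[bad[1]], intervals$start[bad[1]],
            intervals$end[bad[1]], len[bad[1]])
  seqs <- Biostrings::subseq(genome[idx], start = intervals$start + 1L,
                             end = intervals$end)
  toupper(as.character(seqs, use.names = FALSE))
}

#' Read a per-base signal track from a bedGraph file
#'
#' Builds a `signal_track`: a sparse, piecewise-constant non-negative
#' signal.  Lookups outside covered records return 0.
#'
#' @param path 4-column bedGraph (chrom, start, end, value), records
#'   non-overlapping within each chromosome.
#' @param cell_type,assay Labels attached to the track.
#' @return An object of class `signal_track`.
#' @export
read_signal <- function(path, cell_type = "cellA", assay = "DNase") {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"))
  signal_track(as.data.frame(dt), cell_type = cell_type, assay = assay)
}

#' Construct a signal track from an interval/value table
#'
#' @param df Data frame with columns chrom, start, end, value.
#' @param cell_type,assay Labels.
#' @return `signal_track` object.
#' @export
signal_track <- function(df, cell_type = "cellA", assay = "DNase") {
  if (nrow(df)) {
    validate_intervals(df)
    if (any(df$value < 0))
      bs_stop("negative signal value at row %d", which(df$value < 0)[1])
  }
  by_chrom <- split(df[, c("start", "end", "value")], df$chrom)
  by_chrom <- lapply(by_chrom, function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      bs_stop("overlapping bedGraph records on a chromosome")
    d
  })
  structure(list(cell_type = cell_type, assay = assay, data = by_chrom),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track %s/%s: %d record(s) on %d chromosome(s)>\n",
              x$cell_type, x$assay, sum(vapply(x$data, nrow, 0L)),
              length(x$data)))
  invisible(x)
}

#' Per-base signal values over an interval
#'
#' @param track A `signal_track`.
#' @param chrom,start,end Query interval (0-based half-open).
#' @return Numeric vector of length `end - start`; uncovered bases are 0.
#' @export
signal_values <- function(track, chrom, start, end) {
  stopifnot(inherits(track, "signal_track"), end > start)
  out <- numeric(end - start)
  d <- track$data[[chrom]]
  if (is.null(d) || !nrow(d)) return(out)
  pos <- start:(end - 1L)
  idx <- findInterval(pos, d$start)
  hit <- idx > 0L
  hit[hit] <- pos[hit] < d$end[idx[hit]]
  out[hit] <- d$value[idx[hit]]
  out
}

#' Read a Hi-C contact map from triplet text
#'
#' Lines are `chrom bin_start_i bin_start_j count` with bin starts that are
#' multiples of the resolution.  The map is symmetrized on read: entry
#' (i, j) implies entry (j, i).
#'
#' @param path Triplet text file (whitespace- or tab-separated).
#' @param resolution Bin width in bp (default 5000, i.e. 5 kb bins).
#' @param cell_type Label.
#' @return An object of class `contact_map`.
#' @export
read_contacts <- function(path, resolution = 5000L, cell_type = "cellA") {
  dt <- tryCatch(
    suppressWarnings(
      data.table::fread(path, header = FALSE,
                        col.names = c("chrom", "bin_i", "bin_j", "count"))),
    error = function(e) data.table::data.table(
      chrom = character(), bin_i = integer(), bin_j = integer(),
      count = numeric()))
  contact_map(as.data.frame(dt), resolution = resolution,
              cell_type = cell_type)
}

#' Construct a contact map from a triplet table
#'
#' @param df Data frame with columns chrom, bin_i, bin_j, count (bin starts
#'   in bp).
#' @param resolution Bin width in bp; all bin starts must be multiples.
#' @param cell_type Label.
#' @return `contact_map` object with symmetric entries.
#' @export
contact_map <- function(df, resolution = 5000L, cell_type = "cellA") {
  if (resolution <= 0) bs_stop("resolution must be positive")
  dt <- data.table::as.data.table(df)
  if (nrow(dt)) {
    if (any(dt$count < 0)) bs_stop("negative contact count")
    off <- c(dt$bin_i, dt$bin_j) %% resolution
    if (any(off != 0))
      bs_stop("bin start not a multiple of the %d bp resolution", resolution)
    sym <- rbind(dt,
                 dt[, list(chrom = chrom, bin_i = bin_j, bin_j = bin_i,
                           count = count)])
    key <- paste(sym$chrom, sym$bin_i, sym$bin_j)
    agg <- sym[, list(n = length(unique(count))), by = list(chrom, bin_i, bin_j)]
    if (any(agg$n > 1))
      bs_stop("duplicate contact entries with conflicting counts")
    sym <- sym[!duplicated(key)]
  } else {
    sym <- data.table::data.table(chrom = character(), bin_i = integer(),
                                  bin_j = integer(), count = numeric())
  }
  data.table::setkeyv(sym, c("chrom", "bin_i"))
  structure(list(cell_type = cell_type, resolution = as.integer(resolution),
                 entries = sym),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map %s: %d symmetric entries at %d bp resolution>\n",
              x$cell_type, nrow(x$entries), x$resolution))
  invisible(x)
}

#' Contact count for a bin pair
#' @param map A `contact_map`.
#' @param chrom Chromosome name.
#' @param bin_i,bin_j Bin start coordinates in bp.
#' @return The stored count, or 0 if absent.
#' @export
contact_entry <- function(map, chrom, bin_i, bin_j) {
  e <- map$entries
  sel <- which(e[["chrom"]] == chrom & e[["bin_i"]] == bin_i &
                 e[["bin_j"]] == bin_j)
  if (length(sel)) e[["count"]][sel[1]] else 0
}

#' Interacting partner bins of one bin
#' @param map A `contact_map`.
#' @param chrom Chromosome name.
#' @param bin Bin start in bp.
#' @param include_self Keep the diagonal (self-contact) entry?
#' @return Data frame with columns `partner` (bin start) and `count`.
#' @export
contact_partners <- function(map, chrom, bin, include_self = FALSE) {
  e <- map$entries
  sel <- e[["chrom"]] == chrom & e[["bin_i"]] == bin
  if (!include_self) sel <- sel & e[["bin_j"]] != bin
  data.frame(partner = e[["bin_j"]][sel], count = e[["count"]][sel])
}

#' Read position weight matrices from a JASPAR-format file
#'
#' Accepts both the bracketed JASPAR layout (`A [ 1 2 3 ]`) and plain
#' 4-row numeric blocks under each `>id` header.  Matrices are stored as
#' read (typically counts); set `log_odds = TRUE` for an explicit
#' conversion to log2 odds against a uniform background.
#'
#' @param path JASPAR text file.
#' @param log_odds Convert counts to log-odds scores?
#' @param pseudocount Added to column-normalized probabilities before the
#'   log (default 0.01).
#' @param background Background base probability (default uniform 0.25).
#' @return List of `pwm` objects (4 x w matrices, rows A, C, G, T) in file
#'   order.
#' @export
read_pwms <- function(path, log_odds = FALSE, pseudocount = 0.01,
                      background = 0.25) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) bs_stop("no JASPAR '>' headers found in %s", path)
  ends <- c(starts[-1] - 1L, length(lines))
  pwms <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    header <- sub("^>\\s*", "", lines[starts[b]])
    id <- strsplit(header, "\\s+")[[1]][1]
    body <- lines[(starts[b] + 1L):ends[b]]
    if (length(body) != 4L)
      bs_stop("PWM block '%s' has %d base rows, expected 4 (A, C, G, T)",
              id, length(body))
    rows <- lapply(body, function(ln) {
      ln <- gsub("^[ACGTacgt]\\s*", "", ln)
      ln <- gsub("[][]", " ", ln)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    })
    w <- lengths(rows)
    if (length(unique(w)) != 1L)
      bs_stop("PWM block '%s' has unequal row lengths (%s)",
              id, paste(w, collapse = ", "))
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    if (any(!is.finite(m))) bs_stop("non-finite PWM entry in block '%s'", id)
    if (log_odds) m <- pwm_log_odds(m, pseudocount, background)
    pwms[[b]] <- structure(list(id = id, width = ncol(m), weights = m),
                           class = "pwm")
  }
  pwms
}

#' Convert a count PWM to log2-odds weights
#' @param weights 4 x w non-negative count matrix.
#' @param pseudocount Added to probabilities.
#' @param background Background base probability.
#' @return 4 x w log2-odds matrix.
#' @export
pwm_log_odds <- function(weights, pseudocount = 0.01, background = 0.25) {
  p <- sweep(weights, 2, pmax(colSums(weights), .Machine$double.eps), "/")
  log2((p + pseudocount) / (background + pseudocount))
}

#' Construct a PWM object
#' @param id Motif identifier.
#' @param weights 4 x w matrix with rows A, C, G, T.
#' @return `pwm` object.
#' @export
pwm <- function(id, weights) {
  stopifnot(is.matrix(weights), nrow(weights) == 4, ncol(weights) >= 1,
            all(is.finite(weights)))
  rownames(weights) <- c("A", "C", "G", "T")
  structure(list(id = id, width = ncol(weights), weights = weights),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm %s: width %d>\n", x$id, x$width))
  invisible(x)
}

#' Write a feature table as TSV
#'
#' Header columns are `peak_id`, `label`, then one column per feature named
#' `<family>.<name>` (families: seq, motif, chrom, hic).  Round-trips
#' losslessly through [read_feature_table()].
#'
#' @param table A `feature_table` (see [feature_table()]).
#' @param path Output path.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"), nrow(table$x) >= 1)
  cn <- paste(table$families, colnames(table$x), sep = ".")
  if (anyDuplicated(cn))
    bs_stop("duplicate feature name: %s", cn[anyDuplicated(cn)])
  df <- data.frame(peak_id = rownames(table$x),
                   label = if (is.null(table$labels)) NA else table$labels,
                   table$x, check.names = FALSE)
  names(df)[-(1:2)] <- cn
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path TSV path.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  cn <- names(df)[-(1:2)]
  families <- sub("\\..*$", "", cn)
  x <- as.matrix(df[, -(1:2), drop = FALSE])
  colnames(x) <- sub("^[a-z]+\\.", "", cn)
  rownames(x) <- df$peak_id
  labels <- if (all(is.na(df$label))) NULL else df$label
  feature_table(x, families, labels)
}
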