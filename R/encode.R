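## Channel encodings consumed by the convolutional models: one-hot DNA,
## sequence + accessibility (L x 7), and sequence + all landscapes
## (L x 49).

#' One-hot encode a DNA sequence
#'
#' A = (1,0,0,0), C = (0,1,0,0), G = (0,0,1,0), T = (0,0,0,1); N gives an
#' all-zero row.
#'
#' @param seq Uppercase DNA string over A, C, G, T, N.
#' @return `nchar(seq)` x 4 numeric matrix.
#' @export
one_hot <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!ch %in% c("A", "C", "G", "T", "N"))
  if (length(bad))
    bs_stop("invalid base '%s' at position %d", ch[bad[1]], bad[1])
  idx <- match(ch, c("A", "C", "G", "T"))
  m <- matrix(0, length(ch), 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1
  m
}

#' Scale accessibility signal for channel encoding
#'
#' Per-track `asinh` transform followed by max-normalization to `[0, 1]`
#' over the whole dataset (both cell types jointly), applied before the
#' difference channel is computed.  Pass-through when `scale = FALSE`.
#'
#' @param a,b Lists of per-base numeric vectors (one per peak) for the two
#'   cell types.
#' @param scale Apply the transform?
#' @return List with scaled `a` and `b`.
#' @export
scale_accessibility <- function(a, b, scale = TRUE) {
  if (!scale) return(list(a = a, b = b))
  a <- lapply(a, asinh)
  b <- lapply(b, asinh)
  mx <- max(c(unlist(a), unlist(b), 0))
  if (mx > 0) {
    a <- lapply(a, function(v) v / mx)
    b <- lapply(b, function(v) v / mx)
  }
  list(a = a, b = b)
}

#' Encode one peak as sequence + accessibility channels (L x 7)
#'
#' Channels: one-hot DNA (4), accessibility in cell A, accessibility in
#' cell B, and their difference A - B.  Dropping the accessibility
#' channels reproduces the L x 4 sequence-only encoding of the plain
#' sequence CNN.
#'
#' @param seq DNA string of length L.
#' @param dnase_a,dnase_b Per-base accessibility over the peak, length L
#'   each (already scaled; see [scale_accessibility()]).
#' @return L x 7 numeric matrix.
#' @export
encode_cnn_plus <- function(seq, dnase_a, dnase_b) {
  L <- nchar(seq)
  if (length(dnase_a) != L || length(dnase_b) != L)
    bs_stop("length mismatch: seq %d, dnase_a %d, dnase_b %d", L,
            length(dnase_a), length(dnase_b))
  cbind(one_hot(seq), A = dnase_a, B = dnase_b, diff = dnase_a - dnase_b)
}

#' Encode one peak as sequence + all chromatin landscapes (L x 49)
#'
#' Channels: one-hot DNA (4), then per assay in panel order the cell A
#' signal, cell B signal and their difference (15 x 3 = 45), total 49.
#'
#' @param seq DNA string of length L.
#' @param tracks_a,tracks_b Named lists (assay -> per-base numeric vector
#'   of length L) with identical assay sets.
#' @return L x (4 + 3 * n_assays) numeric matrix.
#' @export
encode_cnn_all <- function(seq, tracks_a, tracks_b) {
  L <- nchar(seq)
  assays <- names(tracks_a)
  if (!setequal(assays, names(tracks_b)) || is.null(assays))
    bs_stop("tracks_a and tracks_b must be named lists over the same assays")
  cols <- list(one_hot(seq))
  for (a in assays) {
    va <- tracks_a[[a]]; vb <- tracks_b[[a]]
    if (length(va) != L || length(vb) != L)
      bs_stop("track '%s' length mismatch with sequence length %d", a, L)
    m <- cbind(va, vb, va - vb)
    colnames(m) <- paste0(a, c("_A", "_B", "_diff"))
    cols[[length(cols) + 1L]] <- m
  }
  do.call(cbind, cols)
}

#' Encode a set of peaks into a 3-D array for the CNN
#'
#' @param seqs Character vector of equal-length DNA strings.
#' @param dnase_a,dnase_b Lists of per-base accessibility vectors (needed
#'   for variants other than `"seq"`).
#' @param variant Channel layout: `"plus"` (L x 7), `"seq"` (L x 4),
#'   `"single_a"` / `"single_b"` (one-hot + one cell's accessibility),
#'   `"diff"` (one-hot + difference channel).
#' @param scale Scale accessibility first (see [scale_accessibility()])?
#' @return Numeric array `n x L x C`.
#' @export
encode_dataset <- function(seqs, dnase_a = NULL, dnase_b = NULL,
                           variant = c("plus", "seq", "single_a", "single_b",
                                       "diff"),
                           scale = TRUE) {
  variant <- match.arg(variant)
  n <- length(seqs)
  L <- nchar(seqs[1])
  if (any(nchar(seqs) != L)) bs_stop("sequences must have equal length")
  if (variant != "seq") {
    sc <- scale_accessibility(dnase_a, dnase_b, scale)
    dnase_a <- sc$a; dnase_b <- sc$b
  }
  C <- switch(variant, plus = 7L, seq = 4L, single_a = 5L, single_b = 5L,
              diff = 5L)
  X <- array(0, c(n, L, C))
  for (i in seq_len(n)) {
    oh <- one_hot(seqs[i])
    X[i, , 1:4] <- oh
    if (variant == "plus") {
      X[i, , 5] <- dnase_a[[i]]
      X[i, , 6] <- dnase_b[[i]]
      X[i, , 7] <- dnase_a[[i]] - dnase_b[[i]]
    } else if (variant == "single_a") {
      X[i, , 5] <- dnase_a[[i]]
    } else if (variant == "single_b") {
      X[i, , 5] <- dnase_b[[i]]
    } else if (variant == "diff") {
      X[i, , 5] <- dnase_a[[i]] - dnase_b[[i]]
    }
  }
  X
}
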