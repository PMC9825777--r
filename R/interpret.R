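## Interpretation tools: reference-based per-position attribution for the
## CNN (rescale rule), exact SHAP values for the boosted-tree model,
## accessibility correlation, Jaccard distances and the cross-factor /
## unified-model evaluation protocols.

# multiplier with gradient fallback where the delta vanishes
bs_rescale_ratio <- function(dy, dx, grad, eps = 1e-9) {
  out <- grad
  big <- abs(dx) > eps
  out[big] <- dy[big] / dx[big]
  out
}

#' Per-position contribution scores relative to a masking reference
#'
#' Attribution by the rescale rule: a reference input is built from the
#' example itself by zeroing either the sequence channels (1-4) or the
#' chromatin channels (5..C); multipliers are backpropagated through the
#' dense, ReLU, max-pool and convolutional layers, giving per-channel,
#' per-position contributions whose total equals the margin difference
#' between input and reference (completeness).  Contributions are summed
#' over channels to a length-L profile.
#'
#' @param model A trained `bs_cnn`.
#' @param x One encoded example, `L x C` matrix matching the model.
#' @param reference_kind `"sequence_zeroed"` or `"chromatin_zeroed"`.
#' @param class_index For 3-class models, which class margin to attribute
#'   (default: the predicted class).
#' @param tol Completeness tolerance; larger discrepancies warn.
#' @return Object of class `contribution_profile` with `contributions`
#'   (length L), `channel_contributions` (L x C), `delta` (margin
#'   difference) and `completeness_error`.
#' @export
attribute <- function(model, x,
                      reference_kind = c("sequence_zeroed",
                                         "chromatin_zeroed"),
                      class_index = NULL, tol = 1e-4) {
  reference_kind <- match.arg(reference_kind)
  stopifnot(inherits(model, "bs_cnn"), is.matrix(x))
  L <- nrow(x)
  C <- ncol(x)
  if (L != model$L || C != model$in_channels)
    bs_stop("example is %d x %d; model expects %d x %d", L, C, model$L,
            model$in_channels)
  ref <- x
  if (reference_kind == "sequence_zeroed") {
    ref[, 1:4] <- 0
  } else {
    if (C <= 4) bs_stop("model has no chromatin channels to zero")
    ref[, 5:C] <- 0
  }
  Xx <- array(x, c(1L, L, C))
  Xr <- array(ref, c(1L, L, C))
  cx <- cnn_forward(model, Xx)
  cr <- cnn_forward(model, Xr)
  unit <- if (model$n_out == 1L) 1L else {
    if (is.null(class_index)) which.max(cx$margin[1, ]) else
      as.integer(class_index)
  }
  delta <- cx$margin[1, unit] - cr$margin[1, unit]

  m_A1 <- model$layers$dense2$W[, unit]
  mult_Z1 <- m_A1 * bs_rescale_ratio(cx$A1[1, ] - cr$A1[1, ],
                                     cx$Z1[1, ] - cr$Z1[1, ],
                                     as.numeric(cx$Z1[1, ] > 0))
  m_P <- model$layers$dense1$W %*% mult_Z1 # flat multiplier
  nb <- length(model$spec$blocks)
  last <- model$layers[[nb]]
  dim(m_P) <- c(last$L_pool, last$F)
  for (bi in nb:1) {
    ly <- model$layers[[bi]]
    bx <- cx$blocks[[bi]]
    br <- cr$blocks[[bi]]
    # max-pool: route each pooled delta to the input argmax of x (falling
    # back to the argmax of the reference), preserving completeness
    m_A <- matrix(0, ly$L_out, ly$F)
    dyP <- bx$P - br$P
    for (qf in which(m_P != 0 & abs(dyP) > 0)) {
      q <- (qf - 1L) %% ly$L_pool + 1L
      f <- (qf - 1L) %/% ly$L_pool + 1L
      row1 <- (q - 1L) * ly$pool + bx$am[q, f]
      dx1 <- bx$A[row1, f] - br$A[row1, f]
      if (abs(dx1) > 1e-9) {
        m_A[row1, f] <- m_A[row1, f] + m_P[q, f] * dyP[q, f] / dx1
      } else {
        row2 <- (q - 1L) * ly$pool + br$am[q, f]
        dx2 <- bx$A[row2, f] - br$A[row2, f]
        if (abs(dx2) > 1e-9)
          m_A[row2, f] <- m_A[row2, f] + m_P[q, f] * dyP[q, f] / dx2
      }
    }
    mult_Z <- m_A * bs_rescale_ratio(bx$A - br$A, bx$Z - br$Z,
                                     (bx$Z > 0) * 1)
    m_M <- mult_Z %*% t(ly$W)
    m_X <- matrix(0, ly$L_in, ly$C)
    for (j in seq_len(ly$k)) {
      blk <- m_M[, ((j - 1L) * ly$C + 1L):(j * ly$C), drop = FALSE]
      rows <- j:(j + ly$L_out - 1L)
      m_X[rows, ] <- m_X[rows, ] + blk
    }
    m_P <- m_X
  }
  channel_contrib <- m_P * (x - ref)
  contrib <- rowSums(channel_contrib)
  err <- abs(sum(channel_contrib) - delta)
  if (err > tol)
    warning(sprintf("attribution completeness failure: |sum - delta| = %g",
                    err), call. = FALSE)
  structure(list(reference_kind = reference_kind, contributions = contrib,
                 channel_contributions = channel_contrib, delta = delta,
                 completeness_error = err, class_index = unit),
            class = "contribution_profile")
}

#' @export
print.contribution_profile <- function(x, ...) {
  cat(sprintf(
    "<contribution_profile (%s): L = %d, delta = %.4g, completeness err = %.2g>\n",
    x$reference_kind, length(x$contributions), x$delta,
    x$completeness_error))
  invisible(x)
}

## ---- exact SHAP values for tree ensembles ------------------------------

# expected prediction of one tree with the feature subset S known
# (cover-weighted recursion); exported for use as an oracle building block
tree_expected_value <- function(tree, x, known = rep(TRUE, length(x))) {
  rec <- function(j) {
    feat <- tree[j, 1]
    if (feat < 0) return(tree[j, 5])
    l <- tree[j, 3] + 1
    r <- tree[j, 4] + 1
    if (known[feat + 1]) {
      if (x[feat + 1] < tree[j, 2]) rec(l) else rec(r)
    } else {
      (tree[l, 6] * rec(l) + tree[r, 6] * rec(r)) / tree[j, 6]
    }
  }
  rec(1L)
}

# polynomial-time exact Shapley values of the cover-weighted conditional
# expectation game for a single tree (Lundberg's path algorithm)
tree_shap_single <- function(tree, x, M) {
  phi <- numeric(M)
  unwind <- function(d, z, o, w, i) {
    l <- length(w)
    nn <- w[l]
    if (l >= 2) for (j in (l - 1):1) {
      if (o[i] != 0) {
        t0 <- w[j]
        w[j] <- nn * l / (j * o[i])
        nn <- t0 - w[j] * z[i] * (l - j) / l
      } else {
        w[j] <- w[j] * l / (z[i] * (l - j))
      }
    }
    keep <- setdiff(seq_len(l), i)
    list(d = d[keep], z = z[keep], o = o[keep], w = w[seq_len(l - 1)])
  }
  recurse <- function(j, d, z, o, w, pz, po, pi) {
    # extend the path
    l <- length(w)
    d <- c(d, pi); z <- c(z, pz); o <- c(o, po)
    w <- c(w, if (l == 0) 1 else 0)
    if (l > 0) for (i in l:1) {
      w[i + 1] <- w[i + 1] + po * w[i] * i / (l + 1)
      w[i] <- pz * w[i] * (l + 1 - i) / (l + 1)
    }
    l <- l + 1
    feat <- tree[j, 1]
    if (feat < 0) {
      if (l >= 2) for (i in 2:l) {
        u <- unwind(d, z, o, w, i)
        phi[d[i] + 1] <<- phi[d[i] + 1] +
          sum(u$w) * (o[i] - z[i]) * tree[j, 5]
      }
      return(invisible(NULL))
    }
    lj <- tree[j, 3] + 1
    rj <- tree[j, 4] + 1
    if (x[feat + 1] < tree[j, 2]) { h <- lj; cold <- rj }
    else { h <- rj; cold <- lj }
    iz <- 1; io <- 1
    k <- which(d == feat)[1]
    if (!is.na(k)) {
      iz <- z[k]; io <- o[k]
      u <- unwind(d, z, o, w, k)
      d <- u$d; z <- u$z; o <- u$o; w <- u$w
    }
    recurse(h, d, z, o, w, iz * tree[h, 6] / tree[j, 6], io, feat)
    recurse(cold, d, z, o, w, iz * tree[cold, 6] / tree[j, 6], 0, feat)
  }
  recurse(1L, integer(0), numeric(0), numeric(0), numeric(0), 1, 1, -1L)
  phi
}

#' Exact SHAP values for a boosted-tree model
#'
#' Shapley values of the cover-weighted conditional-expectation game for
#' each tree, summed over the ensemble (the classic polynomial-time tree
#' algorithm).  Additivity holds exactly: base value + row sum = the
#' model's margin output for that row.
#'
#' @param model A `bs_gbt` model.
#' @param X Feature table or matrix of rows to explain.
#' @param class_index For multiclass models, which class's trees to
#'   attribute (1-based; default 1).  Binary models have one tree stream.
#' @return `nrow(X)` x `n_features` matrix with a `base_value` attribute.
#' @export
tree_shap <- function(model, X, class_index = 1L) {
  stopifnot(inherits(model, "bs_gbt"))
  X <- if (inherits(X, "feature_table")) X$x else as.matrix(X)
  M <- ncol(X)
  K <- model$trees_per_round
  use <- seq_len(min(length(model$trees), model$best_iter * K))
  use <- use[(use - 1L) %% K + 1L == class_index]
  phi <- matrix(0, nrow(X), M,
                dimnames = list(rownames(X), model$feature_names))
  base <- 0
  for (t in use) {
    tr <- model$trees[[t]]
    base <- base + tree_expected_value(tr, numeric(M), rep(FALSE, M))
    for (i in seq_len(nrow(X)))
      phi[i, ] <- phi[i, ] + tree_shap_single(tr, X[i, ], M)
  }
  attr(phi, "base_value") <- base
  phi
}

#' Mean absolute SHAP per feature family, stratified by predicted class
#'
#' @param shap SHAP matrix from [tree_shap()].
#' @param families Family tag per column (`seq`, `motif`, `chrom`, `hic`),
#'   e.g. from the model's `families` element.
#' @param predicted_class Per-row predicted class labels (any vector).
#' @return Data frame with columns `class`, `family`, `mean_abs_shap`,
#'   ranked within class.
#' @export
shap_family_summary <- function(shap, families,
                                predicted_class = rep("all", nrow(shap))) {
  if (length(families) != ncol(shap))
    bs_stop("families length (%d) != SHAP columns (%d)", length(families),
            ncol(shap))
  bad <- setdiff(unique(families), c("seq", "motif", "chrom", "hic"))
  if (length(bad))
    bs_stop("unknown family tag: %s", paste(bad, collapse = ", "))
  out <- list()
  for (cl in unique(predicted_class)) {
    rows <- which(predicted_class == cl)
    for (fam in unique(families)) {
      cols <- which(families == fam)
      out[[length(out) + 1L]] <- data.frame(
        class = cl, family = fam,
        n_features = length(cols),
        mean_abs_shap = mean(abs(shap[rows, cols, drop = FALSE])))
    }
  }
  out <- do.call(rbind, out)
  out[order(out$class, -out$mean_abs_shap), ]
}

## ---- signal correlation and interval distances -------------------------

#' Pearson correlation of two signal tracks over each peak
#'
#' Correlates the per-base signal vectors of the two cell types across
#' each peak; zero-variance vectors give `NA` (excluded from any
#' downstream summary).
#'
#' @param peaks Interval data frame (optionally with a `label` column,
#'   copied into the result).
#' @param track_a,track_b `signal_track` objects.
#' @return Data frame with columns `peak_id`, `r` and (if available)
#'   `label`.
#' @export
pearson_signal_correlation <- function(peaks, track_a, track_b) {
  validate_intervals(peaks)
  r <- vapply(seq_len(nrow(peaks)), function(i) {
    va <- signal_values(track_a, peaks$chrom[i], peaks$start[i], peaks$end[i])
    vb <- signal_values(track_b, peaks$chrom[i], peaks$start[i], peaks$end[i])
    if (sd(va) == 0 || sd(vb) == 0) return(NA_real_)
    cor(va, vb)
  }, 0)
  out <- data.frame(peak_id = sprintf("%s:%d-%d", peaks$chrom, peaks$start,
                                      peaks$end),
                    r = r)
  if ("label" %in% names(peaks)) out$label <- peaks$label
  out
}

#' Jaccard distance between two peak sets
#'
#' One minus the ratio of base pairs in the intersection of the two
#' interval unions to base pairs in their union: 0 for identical sets, 1
#' for disjoint ones.
#'
#' @param peaks_x,peaks_y Interval data frames.
#' @return Distance in `[0, 1]`.
#' @export
jaccard_distance <- function(peaks_x, peaks_y) {
  if (!nrow(peaks_x) && !nrow(peaks_y))
    bs_stop("Jaccard distance undefined for two empty peak sets")
  if (!nrow(peaks_x) || !nrow(peaks_y)) return(1)
  chroms <- union(peaks_x$chrom, peaks_y$chrom)
  inter <- 0
  uni <- 0
  for (ch in chroms) {
    ix <- peaks_x[peaks_x$chrom == ch, , drop = FALSE]
    iy <- peaks_y[peaks_y$chrom == ch, , drop = FALSE]
    rx <- IRanges::reduce(IRanges::IRanges(ix$start + 1L, ix$end))
    ry <- IRanges::reduce(IRanges::IRanges(iy$start + 1L, iy$end))
    inter <- inter + sum(IRanges::width(IRanges::intersect(rx, ry)))
    uni <- uni + sum(IRanges::width(IRanges::union(rx, ry)))
  }
  1 - inter / uni
}

## ---- cross-factor protocols -------------------------------------------

bs_predict_scores <- function(model, x) {
  if (inherits(model, "bs_gbt")) predict(model, x)
  else if (inherits(model, "bs_cnn")) predict(model, x)
  else bs_stop("unsupported model class: %s", paste(class(model),
                                                    collapse = "/"))
}

#' Cross-factor evaluation matrix
#'
#' Tests the model trained on each binding factor against every factor's
#' test set in rotation, reporting the PRAUC matrix (rows = training
#' factor, columns = test factor) and, when peak sets are supplied,
#' companion Jaccard distance matrices for the specific and shared peak
#' sets.  All models must share one feature schema (for the tree model,
#' motif features computed against a single pooled PWM panel).
#'
#' @param models Named list of trained models (`bs_gbt` or `bs_cnn`), one
#'   per factor.
#' @param test_sets Named list (same names) of `list(x = , y = )` test
#'   splits in the representation each model consumes.
#' @param peak_sets Optional named list of `list(specific = , shared = )`
#'   interval data frames per factor.
#' @return Object of class `cross_factor_report`: `prauc` matrix, optional
#'   `jaccard_specific` / `jaccard_shared` matrices, `mean_off_diagonal`.
#' @export
cross_factor_eval <- function(models, test_sets, peak_sets = NULL) {
  factors <- names(models)
  if (is.null(factors) || !setequal(factors, names(test_sets)))
    bs_stop("models and test_sets must be named lists over the same factors")
  nc <- vapply(models, function(m)
    if (inherits(m, "bs_gbt")) length(m$feature_names) else m$in_channels, 0)
  if (length(unique(nc)) != 1L)
    bs_stop(paste("feature schemas differ across factors (%s);",
                  "recompute features against a shared panel"),
            paste(unique(nc), collapse = ", "))
  prauc <- matrix(NA_real_, length(factors), length(factors),
                  dimnames = list(train = factors, test = factors))
  for (tr in factors) {
    for (te in factors) {
      ts <- test_sets[[te]]
      sc <- bs_predict_scores(models[[tr]], ts$x)
      prauc[tr, te] <- auc_pr(sc, ts$y)
    }
  }
  out <- list(prauc = prauc,
              mean_off_diagonal = mean(prauc[row(prauc) != col(prauc)]))
  if (!is.null(peak_sets)) {
    jac <- function(kind) {
      m <- matrix(0, length(factors), length(factors),
                  dimnames = list(factors, factors))
      for (a in factors) for (b in factors)
        m[a, b] <- if (a == b) 0 else
          jaccard_distance(peak_sets[[a]][[kind]], peak_sets[[b]][[kind]])
      m
    }
    out$jaccard_specific <- jac("specific")
    out$jaccard_shared <- jac("shared")
  }
  structure(out, class = "cross_factor_report")
}

#' @export
print.cross_factor_report <- function(x, ...) {
  cat(sprintf("<cross_factor_report: %d factors, mean off-diagonal PRAUC %.3f>\n",
              nrow(x$prauc), x$mean_off_diagonal))
  print(round(x$prauc, 3))
  invisible(x)
}

# row-bind n x L x C arrays
bs_pool_arrays <- function(arrays) {
  L <- dim(arrays[[1]])[2]
  C <- dim(arrays[[1]])[3]
  n <- sum(vapply(arrays, function(a) dim(a)[1], 0L))
  out <- array(0, c(n, L, C))
  at <- 0L
  for (a in arrays) {
    out[(at + 1L):(at + dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Leave-one-factor-out unified CNN
#'
#' Pools the training (and validation) splits of every factor except the
#' held-out one, trains a single CNN on the pool and evaluates it on the
#' held-out factor's test split only.  Peak ids, when provided, are
#' checked for train/test leakage.
#'
#' @param datasets Named list per factor, each a list with `train`, `val`,
#'   `test` elements of the form `list(x = <n x L x C array>, y = labels,
#'   ids = optional peak ids)`.
#' @param held_out Name of the factor to hold out.
#' @param spec CNN architecture (a [cnn_spec()]).
#' @param seed Integer seed.
#' @param ... Passed to [train_cnn()].
#' @return List with the trained `model`, held-out `metrics`, `n_train`.
#' @export
train_unified <- function(datasets, held_out, spec = cnn_spec(), seed = 1L,
                          ...) {
  if (!held_out %in% names(datasets))
    bs_stop("held-out factor '%s' not among datasets (%s)", held_out,
            paste(names(datasets), collapse = ", "))
  if (length(datasets) < 2) bs_stop("need at least 2 factors")
  rest <- datasets[setdiff(names(datasets), held_out)]
  test <- datasets[[held_out]]$test
  train_ids <- unlist(lapply(rest, function(d) d$train$ids))
  if (!is.null(train_ids) && !is.null(test$ids) &&
      length(intersect(train_ids, test$ids)))
    bs_stop("peak-id leakage between pooled training and held-out test set")
  X <- bs_pool_arrays(lapply(rest, function(d) d$train$x))
  y <- unlist(lapply(rest, function(d) d$train$y))
  Xv <- bs_pool_arrays(lapply(rest, function(d) d$val$x))
  yv <- unlist(lapply(rest, function(d) d$val$y))
  model <- train_cnn(X, y, Xv, yv, spec = spec, seed = seed, ...)
  sc <- predict(model, test$x)
  task <- if (spec$n_out == 1L) "B" else "C"
  list(model = model, metrics = evaluate(sc, test$y, task),
       n_train = length(y))
}
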