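## A small 1-D convolutional network for channel-encoded peaks: three
## conv/ReLU/max-pool/dropout blocks and a dense head, trained with Adam
## and cross-entropy.  Implemented on batched im2col matrix products so a
## BLAS is the only backend; every stochastic step is driven by an
## explicit seed.

#' Specify the CNN architecture
#'
#' Three convolutional blocks (conv, ReLU, max-pool, dropout) followed by
#' a dense block (hidden units, ReLU, dropout) and a sigmoid output for
#' the binary tasks or a 3-unit softmax for the three-class task.  The
#' default last block has 500 filters so that last-conv-layer feature
#' extraction yields 500 values.
#'
#' @param blocks List of per-block lists with `filters`, `kernel`, `pool`,
#'   `dropout`.
#' @param hidden Hidden units in the dense block.
#' @param head_dropout Dropout rate before the output layer.
#' @param n_out 1 (sigmoid, tasks A/B) or 3 (softmax, task C).
#' @return `cnn_spec` object.
#' @export
cnn_spec <- function(blocks = list(
                       list(filters = 128L, kernel = 15L, pool = 4L,
                            dropout = 0.2),
                       list(filters = 256L, kernel = 5L, pool = 4L,
                            dropout = 0.2),
                       list(filters = 500L, kernel = 3L, pool = 4L,
                            dropout = 0.2)),
                     hidden = 64L, head_dropout = 0.5, n_out = 1L) {
  stopifnot(length(blocks) >= 1, n_out %in% c(1L, 3L))
  for (b in blocks)
    stopifnot(b$filters >= 1, b$kernel >= 1, b$pool >= 1,
              b$dropout >= 0, b$dropout < 1)
  structure(list(blocks = blocks, hidden = as.integer(hidden),
                 head_dropout = head_dropout, n_out = as.integer(n_out)),
            class = "cnn_spec")
}

# minimum input length the pooling cascade supports
cnn_min_length <- function(spec) {
  need <- 1L
  for (b in rev(spec$blocks)) need <- need * b$pool + b$kernel - 1L
  need
}

#' Build an untrained CNN
#'
#' He-initialized weights; the forward pass in evaluation mode is
#' deterministic.
#'
#' @param spec A [cnn_spec()].
#' @param in_channels Input channel count C (4 sequence-only, 7 for
#'   sequence + accessibility, 49 for sequence + all landscapes).
#' @param L Input length in bp (peaks are 600 bp after trimming).
#' @param seed Integer seed for weight initialization.
#' @return Object of class `bs_cnn`.
#' @export
build_cnn <- function(spec, in_channels, L, seed = 1L) {
  if (L < cnn_min_length(spec))
    bs_stop("input length %d too short for the pooling cascade; minimum is %d",
            L, cnn_min_length(spec))
  set.seed(bs_child_seed(seed, "init"))
  layers <- list()
  C <- as.integer(in_channels)
  len <- as.integer(L)
  for (bi in seq_along(spec$blocks)) {
    b <- spec$blocks[[bi]]
    fan_in <- b$kernel * C
    L_out <- len - b$kernel + 1L
    L_pool <- L_out %/% b$pool
    layers[[paste0("conv", bi)]] <- list(
      type = "conv", k = b$kernel, C = C, F = b$filters, pool = b$pool,
      dropout = b$dropout, L_in = len, L_out = L_out, L_pool = L_pool,
      W = matrix(rnorm(fan_in * b$filters, sd = sqrt(2 / fan_in)),
                 fan_in, b$filters),
      b = numeric(b$filters))
    C <- as.integer(b$filters)
    len <- L_pool
  }
  flat <- len * C
  layers$dense1 <- list(type = "dense", W = matrix(
    rnorm(flat * spec$hidden, sd = sqrt(2 / flat)), flat, spec$hidden),
    b = numeric(spec$hidden), dropout = spec$head_dropout)
  layers$dense2 <- list(type = "dense", W = matrix(
    rnorm(spec$hidden * spec$n_out, sd = sqrt(2 / spec$hidden)),
    spec$hidden, spec$n_out), b = numeric(spec$n_out))
  structure(list(spec = spec, layers = layers,
                 in_channels = as.integer(in_channels), L = as.integer(L),
                 n_out = spec$n_out, trained = FALSE),
            class = "bs_cnn")
}

#' @export
print.bs_cnn <- function(x, ...) {
  f <- vapply(x$spec$blocks, function(b) b$filters, 0L)
  cat(sprintf("<bs_cnn: %d x %d input, blocks [%s], %s, %s>\n", x$L,
              x$in_channels, paste(f, collapse = ", "),
              if (x$n_out == 1) "sigmoid" else "softmax(3)",
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# im2col: (n, L_in, C) array -> (n * L_out) x (k * C) matrix, rows ordered
# example-fastest then position
bs_im2col <- function(X, k, L_out) {
  n <- dim(X)[1]
  C <- dim(X)[3]
  M <- matrix(0, n * L_out, k * C)
  for (j in seq_len(k)) {
    blk <- X[, j:(j + L_out - 1L), , drop = FALSE]
    dim(blk) <- c(n * L_out, C)
    M[, ((j - 1L) * C + 1L):(j * C)] <- blk
  }
  M
}

bs_pool_index <- function(n, L_pool, pool, o) {
  i <- rep(seq_len(n), L_pool)
  q <- rep(seq_len(L_pool), each = n)
  i + n * ((q - 1L) * pool + o - 1L)
}

# forward pass; train = TRUE applies (inverted) dropout using the current
# RNG stream and records everything needed for backprop
cnn_forward <- function(model, X, train = FALSE) {
  n <- dim(X)[1]
  cache <- list(n = n, blocks = list())
  A_in <- X
  for (bi in seq_along(model$spec$blocks)) {
    ly <- model$layers[[bi]]
    M <- bs_im2col(A_in, ly$k, ly$L_out)
    Z <- M %*% ly$W
    Z <- sweep(Z, 2, ly$b, "+")
    A <- Z * (Z > 0)
    P <- A[bs_pool_index(n, ly$L_pool, ly$pool, 1L), , drop = FALSE]
    am <- matrix(1L, nrow(P), ncol(P))
    if (ly$pool > 1L) {
      for (o in 2:ly$pool) {
        Ao <- A[bs_pool_index(n, ly$L_pool, ly$pool, o), , drop = FALSE]
        sel <- Ao > P
        P[sel] <- Ao[sel]
        am[sel] <- o
      }
    }
    drop_mask <- NULL
    if (train && ly$dropout > 0) {
      drop_mask <- matrix(
        (runif(length(P)) >= ly$dropout) / (1 - ly$dropout), nrow(P))
      P <- P * drop_mask
    }
    cache$blocks[[bi]] <- list(M = M, Z = Z, A = A, P = P, am = am,
                               drop = drop_mask, A_in = A_in)
    out <- P
    dim(out) <- c(n, ly$L_pool, ly$F)
    A_in <- out
  }
  flat <- A_in
  dim(flat) <- c(n, prod(dim(A_in)[2:3]))
  d1 <- model$layers$dense1
  Z1 <- sweep(flat %*% d1$W, 2, d1$b, "+")
  A1 <- Z1 * (Z1 > 0)
  drop1 <- NULL
  if (train && d1$dropout > 0) {
    drop1 <- matrix((runif(length(A1)) >= d1$dropout) / (1 - d1$dropout),
                    nrow(A1))
    A1 <- A1 * drop1
  }
  d2 <- model$layers$dense2
  margin <- sweep(A1 %*% d2$W, 2, d2$b, "+")
  prob <- if (model$n_out == 1L) {
    1 / (1 + exp(-margin))
  } else {
    e <- exp(margin - apply(margin, 1, max))
    e / rowSums(e)
  }
  cache$flat <- flat
  cache$Z1 <- Z1
  cache$A1 <- A1
  cache$drop1 <- drop1
  cache$margin <- margin
  cache$prob <- prob
  cache
}

# gradients for one batch given dmargin (n x n_out); returns list parallel
# to model$layers with $dW, $db
cnn_backward <- function(model, cache, dmargin) {
  n <- cache$n
  grads <- list()
  d2 <- model$layers$dense2
  grads$dense2 <- list(dW = crossprod(cache$A1, dmargin),
                       db = colSums(dmargin))
  dA1 <- dmargin %*% t(d2$W)
  if (!is.null(cache$drop1)) dA1 <- dA1 * cache$drop1
  dZ1 <- dA1 * (cache$Z1 > 0)
  d1 <- model$layers$dense1
  grads$dense1 <- list(dW = crossprod(cache$flat, dZ1), db = colSums(dZ1))
  dflat <- dZ1 %*% t(d1$W)
  nb <- length(model$spec$blocks)
  last <- model$layers[[nb]]
  dP <- dflat
  dim(dP) <- c(n * last$L_pool, last$F)
  for (bi in nb:1) {
    ly <- model$layers[[bi]]
    ca <- cache$blocks[[bi]]
    if (!is.null(ca$drop)) dP <- dP * ca$drop
    dA <- matrix(0, n * ly$L_out, ly$F)
    for (o in seq_len(ly$pool)) {
      idx <- bs_pool_index(n, ly$L_pool, ly$pool, o)
      dA[idx, ] <- dA[idx, ] + dP * (ca$am == o)
    }
    dZ <- dA * (ca$Z > 0)
    grads[[paste0("conv", bi)]] <- list(dW = crossprod(ca$M, dZ),
                                        db = colSums(dZ))
    if (bi > 1L) {
      dM <- dZ %*% t(ly$W)
      prev <- model$layers[[bi - 1L]]
      dX <- array(0, c(n, ly$L_in, ly$C))
      for (j in seq_len(ly$k)) {
        blk <- dM[, ((j - 1L) * ly$C + 1L):(j * ly$C), drop = FALSE]
        dim(blk) <- c(n, ly$L_out, ly$C)
        dX[, j:(j + ly$L_out - 1L), ] <- dX[, j:(j + ly$L_out - 1L), ] + blk
      }
      dP <- dX
      dim(dP) <- c(n * prev$L_pool, prev$F)
    }
  }
  grads
}

bs_adam_init <- function(model) {
  lapply(model$layers, function(ly)
    list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0))
}

bs_adam_step <- function(model, grads, state, lr, t, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8) {
  for (nm in names(model$layers)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    corr1 <- 1 - beta1^t
    corr2 <- 1 - beta2^t
    model$layers[[nm]]$W <- model$layers[[nm]]$W -
      lr * (s$mW / corr1) / (sqrt(s$vW / corr2) + eps)
    model$layers[[nm]]$b <- model$layers[[nm]]$b -
      lr * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
    state[[nm]] <- s
  }
  list(model = model, state = state)
}

cnn_loss <- function(model, X, y, batch = 512L) {
  n <- dim(X)[1]
  total <- 0
  for (b0 in seq(1L, n, by = batch)) {
    sel <- b0:min(n, b0 + batch - 1L)
    prob <- cnn_forward(model, X[sel, , , drop = FALSE])$prob
    eps <- 1e-12
    if (model$n_out == 1L) {
      p <- pmin(pmax(prob[, 1], eps), 1 - eps)
      total <- total - sum(y[sel] * log(p) + (1 - y[sel]) * log(1 - p))
    } else {
      p <- pmax(prob[cbind(seq_along(sel), y[sel] + 1L)], eps)
      total <- total - sum(log(p))
    }
  }
  total / n
}

# run `epochs` epochs of Adam; mutates and returns the model plus the best
# validation loss seen (with early stopping when patience is finite)
cnn_fit <- function(model, X, y, Xval, yval, lr, epochs, batch_size, seed,
                    patience = Inf, keep_best = FALSE) {
  n <- dim(X)[1]
  state <- bs_adam_init(model)
  t <- 0L
  best <- Inf
  best_layers <- NULL
  best_epoch <- 0L
  history <- numeric(0)
  for (ep in seq_len(epochs)) {
    set.seed(bs_child_seed(seed, paste0("epoch", ep)))
    ord <- sample.int(n)
    for (b0 in seq(1L, n, by = batch_size)) {
      sel <- ord[b0:min(n, b0 + batch_size - 1L)]
      Xb <- X[sel, , , drop = FALSE]
      cache <- cnn_forward(model, Xb, train = TRUE)
      nb <- length(sel)
      if (model$n_out == 1L) {
        dmargin <- matrix((cache$prob[, 1] - y[sel]) / nb, ncol = 1)
      } else {
        Y <- matrix(0, nb, model$n_out)
        Y[cbind(seq_len(nb), y[sel] + 1L)] <- 1
        dmargin <- (cache$prob - Y) / nb
      }
      grads <- cnn_backward(model, cache, dmargin)
      t <- t + 1L
      upd <- bs_adam_step(model, grads, state, lr, t)
      model <- upd$model
      state <- upd$state
    }
    vloss <- cnn_loss(model, Xval, yval)
    history <- c(history, vloss)
    if (vloss < best - 1e-9) {
      best <- vloss
      best_epoch <- ep
      if (keep_best) best_layers <- model$layers
    } else if (ep - best_epoch >= patience) {
      break
    }
  }
  if (keep_best && !is.null(best_layers)) model$layers <- best_layers
  list(model = model, val_loss = best, history = history,
       best_epoch = best_epoch)
}

#' Train the CNN with warm-up restarts and a learning-rate search
#'
#' The warm-up phase trains briefly from several random initializations at
#' each candidate learning rate; the (initialization, rate) pair with the
#' best validation loss is then re-trained in full from its stored
#' initialization, with cross-entropy loss, Adam updates (batch size 300)
#' and early stopping on validation loss.
#'
#' @param X,y Training encodings (`n x L x C` array) and integer labels.
#' @param Xval,yval Validation split (disjoint from training).
#' @param spec A [cnn_spec()]; its `n_out` must match the task.
#' @param lr_grid Candidate learning rates (default
#'   `{0.01, 0.001, 0.0001}`).
#' @param batch_size Minibatch size (default 300).
#' @param seed Integer seed; fixed seeds give identical runs.
#' @param warm_inits Number of random initializations tried (default 3).
#' @param warm_epochs Warm-up epochs per candidate (default 5).
#' @param max_epochs Full-training epoch cap (default 100).
#' @param patience Early-stopping patience in epochs (default 10).
#' @return Trained `bs_cnn` with a `training` element recording the chosen
#'   initialization, learning rate and loss history.
#' @export
train_cnn <- function(X, y, Xval, yval, spec = cnn_spec(),
                      lr_grid = c(0.01, 0.001, 0.0001), batch_size = 300L,
                      seed = 1L, warm_inits = 3L, warm_epochs = 5L,
                      max_epochs = 100L, patience = 10L) {
  if (!length(y) || !length(yval)) bs_stop("empty training or validation split")
  stopifnot(dim(X)[1] == length(y), dim(Xval)[1] == length(yval))
  L <- dim(X)[2]
  C <- dim(X)[3]
  warm <- expand.grid(init = seq_len(warm_inits), lr = lr_grid)
  warm$val_loss <- NA_real_
  for (wi in seq_len(nrow(warm))) {
    m0 <- build_cnn(spec, C, L,
                    seed = bs_child_seed(seed, paste0("warm", warm$init[wi])))
    fit <- cnn_fit(m0, X, y, Xval, yval, warm$lr[wi], warm_epochs,
                   batch_size, seed = bs_child_seed(seed, "warmfit"))
    warm$val_loss[wi] <- fit$val_loss
  }
  best <- which.min(warm$val_loss)
  model <- build_cnn(spec, C, L,
                     seed = bs_child_seed(seed, paste0("warm",
                                                       warm$init[best])))
  fit <- cnn_fit(model, X, y, Xval, yval, warm$lr[best], max_epochs,
                 batch_size, seed = bs_child_seed(seed, "fullfit"),
                 patience = patience, keep_best = TRUE)
  model <- fit$model
  model$trained <- TRUE
  model$training <- list(init = warm$init[best], lr = warm$lr[best],
                         warm = warm, val_loss = fit$val_loss,
                         history = fit$history, best_epoch = fit$best_epoch)
  model
}

#' Predict class probabilities from a CNN
#'
#' @param object A `bs_cnn`.
#' @param newdata `n x L x C` array matching the model's input shape.
#' @param type `"prob"` or `"margin"` (pre-sigmoid/softmax scores).
#' @param ... Unused.
#' @return Numeric vector (sigmoid output) or `n x 3` matrix (softmax).
#' @export
predict.bs_cnn <- function(object, newdata, type = c("prob", "margin"),
                           ...) {
  type <- match.arg(type)
  if (length(dim(newdata)) == 2L)
    dim(newdata) <- c(1L, dim(newdata))
  if (dim(newdata)[3] != object$in_channels)
    bs_stop("encoding has %d channels; model expects %d", dim(newdata)[3],
            object$in_channels)
  out <- matrix(0, dim(newdata)[1], object$n_out)
  for (b0 in seq(1L, dim(newdata)[1], by = 512L)) {
    sel <- b0:min(dim(newdata)[1], b0 + 511L)
    cc <- cnn_forward(object, newdata[sel, , , drop = FALSE])
    out[sel, ] <- if (type == "prob") cc$prob else cc$margin
  }
  if (object$n_out == 1L) out[, 1] else out
}

#' CNN-derived sequence features from the last convolutional layer
#'
#' The global maximum over positions of each last-conv-layer filter
#' activation (post-ReLU, pre-pooling) of a pre-trained model — 500
#' features with the default architecture.
#'
#' @param model A trained `bs_cnn` whose last block has `n_features`
#'   filters.
#' @param X `n x L x C` encoded examples.
#' @param n_features Expected feature count (default 500); mismatching
#'   architectures are an error.
#' @return `n x n_features` matrix.
#' @export
extract_cnn_features <- function(model, X, n_features = 500L) {
  nb <- length(model$spec$blocks)
  Fl <- model$layers[[nb]]$F
  if (Fl != n_features)
    bs_stop("last convolutional block has %d filters; expected %d", Fl,
            n_features)
  if (length(dim(X)) == 2L) dim(X) <- c(1L, dim(X))
  n <- dim(X)[1]
  out <- matrix(0, n, Fl)
  for (b0 in seq(1L, n, by = 256L)) {
    sel <- b0:min(n, b0 + 255L)
    cc <- cnn_forward(model, X[sel, , , drop = FALSE])
    A <- cc$blocks[[nb]]$A
    L_out <- model$layers[[nb]]$L_out
    dim(A) <- c(length(sel), L_out, Fl)
    mx <- A[, 1, ]
    for (pos in seq_len(L_out)[-1]) mx <- pmax(mx, A[, pos, ])
    out[sel, ] <- mx
  }
  out
}
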