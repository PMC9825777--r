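## Gradient-boosted tree classifier: grid search over tree depth and
## learning rate, validation-based early stopping, refit at the chosen
## parameters.

#' The depth / learning-rate grid searched by [train_xgboost()]
#'
#' @param max_depth Candidate tree depths (default `{3, 5, 6, 7, 8}`).
#' @param learning_rate Candidate shrinkage values (default
#'   `{0.001, 0.1, 0.3, 0.5, 1}`).
#' @return Data frame of all depth x rate combinations (5 x 5 = 25 rows by
#'   default).
#' @export
xgb_grid <- function(max_depth = c(3L, 5L, 6L, 7L, 8L),
                     learning_rate = c(0.001, 0.1, 0.3, 0.5, 1)) {
  expand.grid(max_depth = max_depth, learning_rate = learning_rate,
              KEEP.OUT.ATTRS = FALSE)
}

#' Train a gradient-boosted tree classifier with grid search
#'
#' Every grid point is trained with early stopping on validation log loss
#' (up to `nrounds` boosting iterations, default 1000); the final model is
#' then re-fit at the best-performing parameters.  Binary tasks use a
#' logistic objective, the three-class task a softmax objective.
#'
#' @param features A `feature_table` or numeric matrix of training rows.
#' @param labels Integer training labels (0/1 or 0/1/2).
#' @param val_features,val_labels Validation split (disjoint from
#'   training) driving early stopping and grid selection.
#' @param grid Data frame with `max_depth` and `learning_rate` columns
#'   (default [xgb_grid()]).
#' @param nrounds Maximum boosting iterations (default 1000).
#' @param patience Early-stopping patience in rounds (default 50).
#' @param lambda L2 regularization on leaf weights.
#' @param min_child_weight Minimum hessian sum per child.
#' @return Object of class `bs_gbt` with the fitted trees, chosen
#'   parameters, grid results and feature metadata.
#' @export
train_xgboost <- function(features, labels, val_features, val_labels,
                          grid = xgb_grid(), nrounds = 1000L, patience = 50L,
                          lambda = 1, min_child_weight = 1) {
  ft <- if (inherits(features, "feature_table")) features else NULL
  X <- if (is.null(ft)) as.matrix(features) else ft$x
  Xv <- if (inherits(val_features, "feature_table")) val_features$x else
    as.matrix(val_features)
  y <- as.integer(labels)
  yv <- as.integer(val_labels)
  if (anyNA(X) || anyNA(Xv)) bs_stop("missing feature values")
  classes <- sort(unique(y))
  if (length(classes) < 2) bs_stop("training labels contain a single class")
  n_class <- max(length(classes), max(y) + 1L)
  grid$val_loss <- NA_real_
  grid$best_iter <- NA_integer_
  for (gi in seq_len(nrow(grid))) {
    fit <- gbt_train_cpp(X, y, Xv, yv, n_class, grid$max_depth[gi],
                         grid$learning_rate[gi], nrounds, lambda,
                         min_child_weight, patience)
    grid$val_loss[gi] <- fit$best_val_loss
    grid$best_iter[gi] <- fit$best_iter
  }
  best <- which.min(grid$val_loss)
  # refit at the chosen parameters (deterministic, so identical to the
  # grid-search fit at that point)
  fit <- gbt_train_cpp(X, y, Xv, yv, n_class, grid$max_depth[best],
                       grid$learning_rate[best], nrounds, lambda,
                       min_child_weight, patience)
  structure(list(trees = fit$trees, best_iter = fit$best_iter,
                 trees_per_round = fit$trees_per_round, n_class = n_class,
                 params = list(max_depth = grid$max_depth[best],
                               learning_rate = grid$learning_rate[best],
                               lambda = lambda,
                               min_child_weight = min_child_weight),
                 grid = grid,
                 feature_names = colnames(X),
                 families = if (is.null(ft)) NULL else ft$families),
            class = "bs_gbt")
}

#' @export
print.bs_gbt <- function(x, ...) {
  cat(sprintf(
    "<bs_gbt: %d-class, %d boosting rounds, max_depth=%d, eta=%g>\n",
    max(x$n_class, 2), x$best_iter, x$params$max_depth,
    x$params$learning_rate))
  invisible(x)
}

#' Predict from a gradient-boosted tree model
#'
#' @param object A `bs_gbt` model.
#' @param newdata Feature table or matrix with the training columns.
#' @param type `"prob"` for probabilities (vector for binary, matrix for
#'   multiclass) or `"margin"` for raw additive scores.
#' @param ... Unused.
#' @return Probabilities or margins.
#' @export
predict.bs_gbt <- function(object, newdata, type = c("prob", "margin"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "feature_table")) newdata$x else
    as.matrix(newdata)
  margin <- gbt_predict_cpp(object$trees, X, object$n_class,
                            object$best_iter)
  if (object$trees_per_round == 1L) {
    m <- margin[, 1]
    if (type == "margin") return(m)
    1 / (1 + exp(-m))
  } else {
    if (type == "margin") return(margin)
    e <- exp(margin - apply(margin, 1, max))
    e / rowSums(e)
  }
}
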