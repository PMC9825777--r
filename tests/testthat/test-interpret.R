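# Attribution, SHAP, correlation and the cross-factor protocols.

test_that("attribution satisfies completeness and the self-reference case", {
  set.seed(40)
  # random small networks, both reference kinds
  for (trial in 1:4) {
    spec <- cnn_spec(blocks = list(
      list(filters = sample(2:5, 1), kernel = sample(3:7, 1),
           pool = sample(1:3, 1), dropout = 0),
      list(filters = sample(2:6, 1), kernel = 3L, pool = 2L, dropout = 0)),
      hidden = sample(4:10, 1), head_dropout = 0,
      n_out = sample(c(1L, 3L), 1))
    m <- build_cnn(spec, 7, 40, seed = trial * 11)
    x <- matrix(rnorm(40 * 7), 40, 7)
    for (rk in c("sequence_zeroed", "chromatin_zeroed")) {
      pr <- attribute(m, x, rk)
      expect_lt(pr$completeness_error, 1e-4)
      expect_length(pr$contributions, 40)
      expect_true(all(is.finite(pr$contributions)))
    }
  }

  # input identical to its reference: all contributions zero
  m <- build_cnn(tiny_spec(), 7, 40, seed = 2)
  x0 <- matrix(rnorm(40 * 7), 40, 7)
  x0[, 1:4] <- 0
  pr <- attribute(m, x0, "sequence_zeroed")
  expect_equal(pr$delta, 0)
  expect_true(all(pr$contributions == 0))

  expect_error(attribute(build_cnn(tiny_spec(), 4, 40, 1),
                         matrix(0, 40, 4), "chromatin_zeroed"),
               "no chromatin channels")
})

test_that("tree_shap matches brute-force Shapley enumeration on <= 4 features", {
  set.seed(41)
  n <- 80
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- as.integer(X[, 1] - X[, 2] * X[, 3] + rnorm(n, sd = 0.3) > 0)
  fit <- train_xgboost(X[1:60, ], y[1:60], X[61:80, ], y[61:80],
                       grid = xgb_grid(3L, 0.3), nrounds = 8, patience = 50)
  use <- fit$trees[seq_len(fit$best_iter)]
  sh <- tree_shap(fit, X[1:5, ])
  for (i in 1:5)
    expect_equal(unname(sh[i, ]), brute_shapley(use, X[i, ], 4),
                 tolerance = 1e-10)
  # additivity: base + sum(shap) = margin
  marg <- predict(fit, X[1:5, ], type = "margin")
  expect_equal(attr(sh, "base_value") + rowSums(sh), marg,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("a depth-1 stump attributes everything to its split feature", {
  set.seed(42)
  X <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  y <- as.integer(X[, 1] > 0)
  fit <- train_xgboost(X[1:70, ], y[1:70], X[71:100, ], y[71:100],
                       grid = xgb_grid(1L, 0.5), nrounds = 1, patience = 5)
  sh <- tree_shap(fit, X[1:10, ])
  expect_true(all(sh[, "b"] == 0))
  marg <- predict(fit, X[1:10, ], type = "margin")
  expect_equal(attr(sh, "base_value") + sh[, "a"], marg,
               ignore_attr = TRUE)
})

test_that("shap_family_summary ranks the planted family first", {
  sh <- matrix(0, 10, 6)
  families <- c("motif", "motif", "chrom", "chrom", "hic", "hic")
  expect_true(all(shap_family_summary(sh, families)$mean_abs_shap == 0))

  set.seed(43)
  sh[, 3:4] <- rnorm(20, sd = 3) # chromatin columns carry the signal
  sh[, c(1:2, 5:6)] <- rnorm(40, sd = 0.1)
  sm <- shap_family_summary(sh, families)
  expect_equal(sm$family[1], "chrom")

  # family means combine back to the overall mean |SHAP|
  expect_equal(sum(sm$mean_abs_shap * sm$n_features) / ncol(sh),
               mean(abs(sh)))
  expect_error(shap_family_summary(sh, rep("bogus", 6)), "unknown family")
})

test_that("SHAP family analysis of a trained model finds the planted chromatin signal", {
  # accessibility-only world (no planted motif): the class signal lives
  # solely in the chromatin features, so that family must dominate
  if (is.null(bs_test_cache$nomotif_small))
    bs_test_cache$nomotif_small <-
      make_bundle(small_config(seed = 2, plant_motif = FALSE))
  b <- bs_test_cache$nomotif_small
  ft <- bundle_features(b)
  y <- as.integer(b$truth$truth == "SHARED")
  tr <- seq_len(60)
  va <- 61:90
  fit <- train_xgboost(ft$x[tr, ], y[tr], ft$x[va, ], y[va],
                       grid = xgb_grid(3L, 0.3), nrounds = 60,
                       patience = 10)
  sh <- tree_shap(fit, ft$x[va, ])
  pred <- ifelse(predict(fit, ft$x[va, ]) > 0.5, "shared", "specific")
  sm <- shap_family_summary(sh, ft$families, pred)
  for (cl in unique(pred)) {
    top <- sm[sm$class == cl, ][1, ]
    expect_equal(top$family, "chrom")
  }
})

test_that("pearson_signal_correlation handles constants and sign flips", {
  v <- data.frame(chrom = "chr1", start = 0:9 * 10, end = 0:9 * 10 + 10,
                  value = c(1, 3, 2, 5, 4, 6, 5, 8, 7, 9))
  ta <- signal_track(v, "cellA", "DNase")
  tb_same <- signal_track(v, "cellB", "DNase")
  neg <- v
  neg$value <- 10 - v$value
  tb_neg <- signal_track(neg, "cellB", "DNase")
  pk <- genomic_intervals("chr1", 0, 100)
  expect_equal(pearson_signal_correlation(pk, ta, tb_same)$r, 1)
  expect_equal(pearson_signal_correlation(pk, ta, tb_neg)$r, -1)
  flat <- signal_track(data.frame(chrom = "chr1", start = 0, end = 100,
                                  value = 2), "cellB", "DNase")
  expect_true(is.na(pearson_signal_correlation(pk, ta, flat)$r))
})

test_that("jaccard_distance is a base-pair metric", {
  a <- genomic_intervals("chr1", 0, 100)
  b <- genomic_intervals("chr1", 50, 150)
  c_ <- genomic_intervals("chr1", 200, 300)
  expect_equal(jaccard_distance(a, a), 0)
  expect_equal(jaccard_distance(a, c_), 1)
  expect_equal(jaccard_distance(a, b), 1 - 50 / 150)
  expect_error(jaccard_distance(a[0, ], a[0, ]), "empty")

  set.seed(44)
  sets <- lapply(1:4, function(i) {
    s <- sort(sample(0:500, 4)) * 10
    genomic_intervals("chr1", s, s + sample(50:200, 4))
  })
  for (i in 1:4) for (j in 1:4) {
    dij <- jaccard_distance(sets[[i]], sets[[j]])
    expect_equal(dij, jaccard_distance(sets[[j]], sets[[i]]))
    for (k in 1:4)
      expect_lte(dij, jaccard_distance(sets[[i]], sets[[k]]) +
                   jaccard_distance(sets[[k]], sets[[j]]) + 1e-12)
  }
})

test_that("cross_factor_eval's diagonal equals within-factor evaluation", {
  set.seed(45)
  make_factor <- function(flip = FALSE) {
    n <- 240
    X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
    sig <- if (flip) -X[, 2] else X[, 2]
    y <- as.integer(sig + rnorm(n, sd = 0.4) > 0)
    list(train = list(x = X[1:140, ], y = y[1:140]),
         val = list(x = X[141:180, ], y = y[141:180]),
         test = list(x = X[181:240, ], y = y[181:240]))
  }
  fa <- make_factor()
  fb <- make_factor()
  fc <- make_factor(flip = TRUE) # anti-pattern factor
  models <- lapply(list(A = fa, B = fb, C = fc), function(d)
    train_xgboost(d$train$x, d$train$y, d$val$x, d$val$y,
                  grid = xgb_grid(3L, 0.3), nrounds = 60, patience = 10))
  tests <- list(A = fa$test, B = fb$test, C = fc$test)
  rep <- cross_factor_eval(models, tests)
  expect_equal(dim(rep$prauc), c(3L, 3L))
  for (f in c("A", "B", "C"))
    expect_equal(rep$prauc[f, f],
                 evaluate(bindspec:::bs_predict_scores(models[[f]],
                                                       tests[[f]]$x),
                          tests[[f]]$y, "B")$prauc)
  # shared planted pattern transfers; the anti-pattern does not
  expect_gt(rep$prauc["A", "B"], 0.8)
  expect_lt(rep$prauc["A", "C"], 0.5)

  peak_sets <- list(
    A = list(specific = genomic_intervals("chr1", 0, 100),
             shared = genomic_intervals("chr1", 500, 600)),
    B = list(specific = genomic_intervals("chr1", 0, 100),
             shared = genomic_intervals("chr1", 550, 650)),
    C = list(specific = genomic_intervals("chr1", 1000, 1100),
             shared = genomic_intervals("chr1", 2000, 2100)))
  rep2 <- cross_factor_eval(models, tests, peak_sets)
  expect_equal(diag(rep2$jaccard_specific), rep(0, 3), ignore_attr = TRUE)
  expect_equal(rep2$jaccard_specific["A", "B"], 0)
  expect_equal(rep2$jaccard_specific["A", "C"], 1)
  expect_equal(rep2$jaccard_shared["A", "B"], 1 - 50 / 150)
})

test_that("train_unified pools every factor except the held-out one", {
  set.seed(46)
  make_enc_factor <- function(id) {
    n <- 60; L <- 24
    y <- rbinom(n, 1, 0.5)
    X <- array(rnorm(n * L * 5), c(n, L, 5))
    X[, , 5] <- X[, , 5] + 1.5 * y
    ids <- paste0(id, "_", seq_len(n))
    list(train = list(x = X[1:30, , ], y = y[1:30], ids = ids[1:30]),
         val = list(x = X[31:45, , ], y = y[31:45], ids = ids[31:45]),
         test = list(x = X[46:60, , ], y = y[46:60], ids = ids[46:60]))
  }
  ds <- list(f1 = make_enc_factor("f1"), f2 = make_enc_factor("f2"),
             f3 = make_enc_factor("f3"))
  spec <- cnn_spec(blocks = list(
    list(filters = 3L, kernel = 5L, pool = 2L, dropout = 0),
    list(filters = 4L, kernel = 3L, pool = 2L, dropout = 0)),
    hidden = 6L, head_dropout = 0, n_out = 1L)
  res <- train_unified(ds, "f3", spec = spec, seed = 3,
                       lr_grid = 0.01, warm_inits = 1L, warm_epochs = 1L,
                       max_epochs = 8L, patience = 3L, batch_size = 30L)
  expect_equal(res$n_train, 60L) # sum of the two retained training splits
  expect_named(res$metrics, c("auc", "prauc"))

  # leakage detection via shared peak ids
  leaky <- ds
  leaky$f1$train$ids[1] <- leaky$f3$test$ids[1]
  expect_error(train_unified(leaky, "f3", spec = spec, seed = 3,
                             lr_grid = 0.01, warm_inits = 1L,
                             warm_epochs = 1L, max_epochs = 2L,
                             batch_size = 30L), "leakage")
  expect_error(train_unified(ds, "nope", spec = spec), "not among")
})
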