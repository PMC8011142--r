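test_that("correlation pruning removes one of a perfectly correlated pair", {
  set.seed(1)
  f1 <- rnorm(50)
  X <- cbind(f1 = f1, f2 = 2 * f1, f3 = rnorm(50))
  kept <- prune_correlated_features(X, 0.7)
  expect_length(intersect(c("f1", "f2"), kept), 1L)
  expect_true("f3" %in% kept)

  Xlow <- cbind(a = rnorm(100), b = rnorm(100), c = rnorm(100))
  expect_setequal(prune_correlated_features(Xlow, 0.7), c("a", "b", "c"))
})

test_that("pruning matches the step-by-step oracle and is idempotent", {
  for (seed in 1:20) {
    set.seed(seed)
    base <- matrix(rnorm(60 * 4), 60, 4)
    # build 10 features as random mixtures so correlation structure varies
    W <- matrix(rnorm(4 * 10), 4, 10)
    X <- base %*% W + matrix(rnorm(600, sd = 0.5), 60, 10)
    colnames(X) <- paste0("f", 1:10)
    kept <- prune_correlated_features(X, 0.7)
    expect_identical(kept, oracle_prune(X, 0.7))
    # pruning the pruned table removes nothing further
    if (length(kept) >= 2L)
      expect_identical(prune_correlated_features(X[, kept], 0.7), kept)
  }
})

test_that("constant feature columns are never removed for constancy alone", {
  set.seed(2)
  X <- cbind(flat = rep(1, 40), g1 = rnorm(40))
  X <- cbind(X, g2 = X[, "g1"] + rnorm(40, sd = 0.01))
  kept <- prune_correlated_features(X, 0.7)
  expect_true("flat" %in% kept)
  expect_length(kept, 2L)
})

test_that("all six methods separate a linearly separable problem on training data", {
  d <- separable_xy()
  for (m in c("lda", "dt", "svm", "rf", "ann", "xgboost")) {
    fit <- etho_fit(d$X, d$y, m, seed = 7)
    expect_equal(mean(predict(fit, d$X) == d$y), 1.0, info = m)
  }
})

test_that("seeded fits are reproducible and ignore row order at prediction", {
  p <- synth_preset("separated4")
  bouts <- generate_labelled_bouts(p$specs, 15, 40, 10.54, seed = 4)
  ft <- feature_table(bouts, "simplified", placement = "back")
  X <- as.matrix(ft[, -(1:2)]); y <- ft$label
  set.seed(99)
  Xt <- X + rnorm(length(X), sd = 0.01)
  for (m in c("ann", "rf", "xgboost")) {
    f1 <- etho_fit(X, y, m, feature_set = "simplified", seed = 11)
    f2 <- etho_fit(X, y, m, feature_set = "simplified", seed = 11)
    expect_identical(predict(f1, Xt), predict(f2, Xt), info = m)
    # permuting prediction rows permutes predictions identically
    perm <- sample(nrow(Xt))
    expect_identical(predict(f1, Xt[perm, ]), predict(f1, Xt)[perm],
                     info = m)
  }
})

test_that("a duplicated feature column leaves seeded predictions deterministic", {
  d <- separable_xy()
  Xd <- cbind(d$X, f1_copy = d$X[, "f1"])
  for (m in c("rf", "xgboost")) {
    f1 <- etho_fit(Xd, d$y, m, seed = 5)
    f2 <- etho_fit(Xd, d$y, m, seed = 5)
    expect_identical(predict(f1, Xd), predict(f2, Xd), info = m)
  }
})

test_that("prediction validates feature columns and finiteness", {
  d <- separable_xy()
  fit <- etho_fit(d$X, d$y, "dt")
  bad <- d$X[, c("f1", "f2")]
  expect_error(predict(fit, bad), "missing: \\[f3\\]")
  extra <- cbind(d$X, f9 = 1)
  expect_error(predict(fit, extra), "extra: \\[f9\\]")
  Xna <- d$X; Xna[3, 2] <- NA
  expect_error(etho_fit(Xna, d$y, "dt"), "feature 'f2', bout 3")
  expect_error(predict(fit, Xna), "non-finite")
  # single-row prediction works
  expect_length(predict(fit, d$X[1, , drop = FALSE]), 1L)
})

test_that("ensemble-size defaults depend on the feature set", {
  d <- separable_xy()
  full <- etho_fit(d$X, d$y, "rf", feature_set = "full")
  simp <- etho_fit(d$X, d$y, "rf", feature_set = "simplified")
  expect_equal(full$hyperparams$ntree, 800L)
  expect_equal(simp$hyperparams$ntree, 20L)
  expect_equal(etho_fit(d$X, d$y, "xgboost")$hyperparams$nrounds, 10L)
  expect_equal(etho_fit(d$X, d$y, "xgboost",
                        feature_set = "simplified")$hyperparams$nrounds, 5L)
})

test_that("a reduced forest stays within a few points of the large one", {
  p <- synth_preset("separated4")
  tr <- generate_labelled_bouts(p$specs, 40, 40, 10.54, seed = 31)
  te <- generate_labelled_bouts(p$specs, 40, 40, 10.54, seed = 32)
  ftr <- feature_table(tr, "simplified", placement = "back")
  fte <- feature_table(te, "simplified", placement = "back")
  Xtr <- as.matrix(ftr[, -(1:2)]); Xte <- as.matrix(fte[, -(1:2)])
  small <- etho_fit(Xtr, ftr$label, "rf", hyperparams = list(ntree = 20L),
                    seed = 1)
  big <- etho_fit(Xtr, ftr$label, "rf", hyperparams = list(ntree = 800L),
                  seed = 1)
  acc_small <- mean(predict(small, Xte) == fte$label)
  acc_big <- mean(predict(big, Xte) == fte$label)
  expect_lte(abs(acc_big - acc_small), 0.05)
})

test_that("grid tuning returns the accuracy-maximising candidate", {
  d <- separable_xy(n_per = 25)
  single <- tune_classifier("dt", d$X, d$y, list(cp = 0.05), k = 5,
                            seed = 3)
  expect_equal(single$best$cp, 0.05)

  # oracle: explicit loop over candidates with the same folds and fits
  p <- synth_preset("separated4")
  bouts <- generate_labelled_bouts(p$specs, 12, 40, 10.54, seed = 13)
  ft <- feature_table(bouts, "simplified", placement = "back")
  X <- as.matrix(ft[, -(1:2)]); y <- ft$label
  grid <- list(cp = c(0.5, 0.05, 0.005))
  tuned <- tune_classifier("dt", X, y, grid, k = 4, seed = 17)
  folds <- stratified_folds(y, k = 4, seed = 17)
  accs <- vapply(sort(grid$cp, decreasing = TRUE), function(cp) {
    mean(vapply(1:4, function(f) {
      m <- etho_fit(X[folds != f, ], y[folds != f], "dt",
                    hyperparams = list(cp = cp), seed = 17 + f)
      mean(predict(m, X[folds == f, ]) == y[folds == f])
    }, numeric(1)))
  }, numeric(1))
  best_oracle <- sort(grid$cp, decreasing = TRUE)[which.max(accs)]
  expect_equal(tuned$best$cp, best_oracle)
  expect_equal(sort(tuned$results$cv_accuracy), sort(unname(accs)))
  expect_error(tune_classifier("dt", X, y, list(), k = 4), "empty")
})
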