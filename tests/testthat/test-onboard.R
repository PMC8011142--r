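# hand-built compact models exercise the engines on closed-form cases

hand_svm <- function(coef = 0.7, rho = 0.3, gamma = 1) {
  structure(list(
    type = "svm",
    SV = matrix(0, 1, 1), coefs = matrix(coef, 1, 1),
    rho = rho, nSV = c(1L, 0L),
    x_center = 0, x_scale = 1, gamma = gamma,
    class_order = c("pos", "neg"), class_labels = c("neg", "pos"),
    feature_names = "f1"),
    class = c("compact_svm", "compact_model"))
}

test_that("single-support-vector SVM decides by the sign of coef - rho", {
  # query equals the SV: kernel = 1, decision = coef - rho
  expect_equal(as.character(predict_compact_svm(hand_svm(0.7, 0.3), 0)),
               "pos")
  expect_equal(as.character(predict_compact_svm(hand_svm(0.7, 1.0), 0)),
               "neg")
  # query far from the SV with a huge gamma: kernel -> 0, sign(-rho)
  expect_equal(as.character(predict_compact_svm(hand_svm(5, 0.3,
                                                         gamma = 1e6), 10)),
               "neg")
  expect_equal(as.character(predict_compact_svm(hand_svm(5, -0.3,
                                                         gamma = 1e6), 10)),
               "pos")
})

hand_ann <- function(W1, b1, W2, b2, labels) {
  structure(list(
    type = "ann", layer_sizes = c(ncol(W1), nrow(W1), nrow(W2)),
    W1 = W1, b1 = b1, W2 = W2, b2 = b2,
    x_center = rep(0, ncol(W1)), x_scale = rep(1, ncol(W1)),
    class_labels = labels, feature_names = paste0("f", seq_len(ncol(W1)))),
    class = c("compact_ann", "compact_model"))
}

test_that("ANN forward pass matches the closed-form logistic composition", {
  # all-zero weights: uniform softmax, alphabetically first class wins
  m0 <- hand_ann(matrix(0, 2, 1), 0, matrix(0, 2, 2), c(0, 0),
                 c("walk", "rest"))
  p0 <- predict_compact_ann(m0, 0.5)
  expect_equal(as.character(p0), "rest")
  expect_true(attr(p0, "ties"))
  # one hidden unit: h = logistic(2x + 1); outputs h and -h
  m1 <- hand_ann(matrix(2, 1, 1), 1, matrix(c(1, -1), 2, 1), c(0, 0),
                 c("up", "down"))
  h <- 1 / (1 + exp(-(2 * 0.3 + 1)))
  expected <- c("up", "down")[which.max(c(h, -h))]
  expect_equal(as.character(predict_compact_ann(m1, 0.3)), expected)
  expect_equal(as.character(predict_compact_ann(m1, -10)), "up") # h>0 always
})

stump <- function(feature, threshold, left_class, right_class) {
  m <- rbind(c(feature, threshold, 2, 3, 0),
             c(0, 0, 0, 0, left_class),
             c(0, 0, 0, 0, right_class))
  colnames(m) <- c("feature", "threshold", "left", "right", "leaf")
  m
}

test_that("forest traversal follows the strict-less-than threshold rule", {
  m <- structure(list(
    type = "forest", trees = list(stump(1, 0.5, 1, 2)), ntree = 1L,
    class_labels = c("low", "high"), feature_names = "f1"),
    class = c("compact_forest", "compact_model"))
  expect_equal(as.character(predict_compact_forest(m, 0.49)), "low")
  expect_equal(as.character(predict_compact_forest(m, 0.5)), "high")
  # all trees identical: vote equals the single-tree output
  m5 <- m; m5$trees <- rep(m$trees, 5); m5$ntree <- 5L
  expect_equal(as.character(predict_compact_forest(m5, c(f1 = 0.2))), "low")
})

test_that("boost engine sums per-class leaf scores and takes the argmax", {
  leaf <- function(score) {
    t <- matrix(c(0, score, 0, 0, 1), 1, 5)
    colnames(t) <- c("feature", "threshold", "left", "right", "leaf")
    t
  }
  tree_a <- rbind(c(1, 0, 2, 3, 0),     # split on f1 at 0
                  c(0, -1, 0, 0, 1),    # left leaf, score -1
                  c(0, 2, 0, 0, 1))     # right leaf, score 2
  colnames(tree_a) <- c("feature", "threshold", "left", "right", "leaf")
  m <- structure(list(
    type = "boost",
    trees = list(tree_a, leaf(0.5), leaf(1.5)),
    nrounds = 1L, n_class = 3L,
    class_labels = c("a", "b", "c"), feature_names = "f1"),
    class = c("compact_boost", "compact_model"))
  # x = -1: class a tree reaches leaf -1; margins (-1, 0.5, 1.5) -> "c"
  expect_equal(as.character(predict_compact_boost(m, -1)), "c")
  # x = 1: margins (2, 0.5, 1.5) -> "a"
  expect_equal(as.character(predict_compact_boost(m, 1)), "a")
  m$trees <- m$trees[1:2]
  expect_error(predict_compact_boost(m, 0), "nrounds")
  # zero trees: all margins zero, alphabetically first class
  m0 <- m; m0$trees <- list(); m0$nrounds <- 0L
  p <- predict_compact_boost(m0, 0)
  expect_equal(as.character(p), "a")
  expect_true(attr(p, "ties"))
})

test_that("malformed trees are rejected", {
  bad <- stump(1, 0.5, 1, 2)
  bad[1, "left"] <- 1   # self-loop
  expect_error(ethoclass:::validate_tree(bad), "malformed")
  bad2 <- stump(1, 0.5, 1, 2)
  bad2[1, "right"] <- 9 # out of range
  expect_error(ethoclass:::validate_tree(bad2), "malformed")
})

test_that("export is restricted to on-board methods and is idempotent", {
  d <- separable_xy()
  expect_error(export_compact(etho_fit(d$X, d$y, "lda")), "on-board")
  expect_error(export_compact(etho_fit(d$X, d$y, "dt")), "on-board")
  expect_error(export_compact(list()), "trained")
  fit <- etho_fit(d$X, d$y, "svm")
  cm <- export_compact(fit)
  expect_identical(export_compact(cm), cm)
})

test_that("exported models are self-contained and reproduce backend predictions", {
  p <- synth_preset("separated4")
  tr <- generate_labelled_bouts(p$specs, 25, 40, 10.54, seed = 61)
  te <- generate_labelled_bouts(p$specs, 25, 40, 10.54, seed = 62)
  ftr <- feature_table(tr, "simplified", placement = "back")
  fte <- feature_table(te, "simplified", placement = "back")
  X <- as.matrix(ftr[, -(1:2)]); Xt <- as.matrix(fte[, -(1:2)])
  for (m in c("svm", "ann", "rf", "xgboost")) {
    fit <- etho_fit(X, ftr$label, m, feature_set = "simplified", seed = 21)
    cmp <- export_compact(fit)
    pc <- predict(cmp, Xt)
    pb <- predict(fit, Xt)
    ok <- !attr(pc, "ties")
    expect_equal(as.character(pc)[ok], pb[ok], info = m)
    # JSON round trip preserves predictions exactly
    f <- withr::local_tempfile(fileext = ".json")
    write_compact_json(cmp, f)
    expect_identical(as.character(predict(read_compact_json(f), Xt)),
                     as.character(pc), info = m)
  }
  fit_rf <- etho_fit(X, ftr$label, "rf", feature_set = "simplified")
  expect_equal(export_compact(fit_rf)$ntree, 20L)
})

test_that("storage accounting counts parameters at the configured width", {
  ann <- hand_ann(matrix(0, 4, 5), rep(0, 4), matrix(0, 3, 4), rep(0, 3),
                  c("a", "b", "c"))
  rep1 <- model_storage_bytes(ann, value_bytes = 4)
  expect_equal(rep1$total_bytes, (5 * 4 + 4 + 4 * 3 + 3 + 2 * 5) * 4)
  expect_equal(rep1$total_bytes, 196)
  expect_equal(sum(rep1$components), rep1$total_bytes)

  forest1 <- structure(list(type = "forest",
                            trees = list(stump(1, 0.5, 1, 2)), ntree = 1L,
                            class_labels = c("a", "b"),
                            feature_names = "f1"),
                       class = c("compact_forest", "compact_model"))
  forest2 <- forest1
  forest2$trees <- rep(forest1$trees, 2); forest2$ntree <- 2L
  expect_equal(model_storage_bytes(forest2)$total_bytes,
               2 * model_storage_bytes(forest1)$total_bytes)

  svm <- hand_svm()
  rep_svm <- model_storage_bytes(svm, value_bytes = 4)
  expect_named(rep_svm$components, c("SV", "coefs", "rho", "scale"))
  # an extra support vector can only increase the footprint
  svm2 <- svm
  svm2$SV <- rbind(svm$SV, 1); svm2$coefs <- rbind(svm$coefs, 0.1)
  svm2$nSV <- c(1L, 1L)
  expect_gt(model_storage_bytes(svm2)$total_bytes, rep_svm$total_bytes)
  # an extra hidden unit can only increase the footprint
  ann2 <- hand_ann(matrix(0, 5, 5), rep(0, 5), matrix(0, 3, 5), rep(0, 3),
                   c("a", "b", "c"))
  expect_gt(model_storage_bytes(ann2)$total_bytes, rep1$total_bytes)
})

test_that("deployment arithmetic is exact at logger scales", {
  expect_equal(compression_ratio(40, 3, 2, 1), 240)
  expect_equal(compression_ratio(1, 3, 2, 1), 6)
  expect_equal(compression_ratio(30, 3, 2, 1), 180)
  expect_equal(storage_days(2^20, 3.8), 46)
  expect_equal(storage_days(86400, 1), 1)
  expect_equal(storage_days(2^20, 60), 728)
  expect_error(compression_ratio(0), "positive")
  expect_error(storage_days(-1, 3.8), "positive")
})
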