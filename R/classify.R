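#' Remove highly correlated features
#'
#' Iterative pruning on the absolute Pearson correlation matrix, the
#' standard pre-processing step for correlation-sensitive classifiers
#' such as LDA: while any off-diagonal absolute correlation exceeds
#' `cutoff`, take the pair with the largest absolute correlation and
#' drop the member whose mean absolute correlation against all remaining
#' features is larger (ties drop the later column). Constant columns
#' have all their correlations treated as 0 and are never removed for
#' constancy alone.
#'
#' @param feature_table Numeric matrix or data frame of features
#'   (columns) by bouts (rows); at least 2 columns.
#' @param cutoff Absolute-correlation threshold in (0, 1); default 0.7.
#' @return Character vector of retained feature names, in original
#'   column order. The procedure is idempotent.
#' @export
prune_correlated_features <- function(feature_table, cutoff = 0.7) {
  X <- as.matrix(feature_table)
  p <- ncol(X)
  if (p < 2L) stop("need at least 2 features", call. = FALSE)
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0,1)",
                                       call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(p))
  C <- suppressWarnings(abs(cor(X)))
  C[!is.finite(C)] <- 0                 # constant columns
  diag(C) <- 0
  keep <- seq_len(p)
  while (length(keep) >= 2L) {
    Cs <- C[keep, keep, drop = FALSE]
    mx <- max(Cs)
    if (mx <= cutoff) break
    hit <- which(Cs == mx, arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    i <- keep[hit[1L, 1L]]; j <- keep[hit[1L, 2L]]
    mean_i <- mean(C[i, setdiff(keep, i)])
    mean_j <- mean(C[j, setdiff(keep, j)])
    drop <- if (mean_i > mean_j) i else if (mean_j > mean_i) j else max(i, j)
    keep <- setdiff(keep, drop)
  }
  colnames(X)[keep]
}

# method-specific default hyperparameters; the reduced-model defaults
# (ntree = 20, nrounds = 5) mirror the model-shrinking step used before
# on-board export
default_hyperparams <- function(method, p, feature_set) {
  switch(method,
    lda = list(cutoff = 0.7),
    dt = list(cp = 0.01),
    svm = list(gamma = 1 / p, cost = 1),
    rf = list(ntree = if (feature_set == "full") 800L else 20L,
              mtry = max(1L, floor(sqrt(p)))),
    ann = list(size = 5L, decay = 0.1, maxit = 500L),
    xgboost = list(nrounds = if (feature_set == "full") 10L else 5L,
                   max_depth = 6L, eta = 0.3))
}

check_feature_matrix <- function(x) {
  X <- as.matrix(x)
  if (!is.numeric(X)) stop("features must be numeric", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  bad <- which(!is.finite(X), arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad)) > 0)
    stop(sprintf("non-finite feature value: feature '%s', bout %d",
                 colnames(X)[bad[1L, 2L]], bad[1L, 1L]), call. = FALSE)
  X
}

#' Fit a behaviour classifier
#'
#' One interface over the six supervised methods used for ACC behaviour
#' classification: linear discriminant analysis (`"lda"`, with
#' correlated features pruned at cutoff 0.7 beforehand), a decision tree
#' (`"dt"`, rpart), a radial-kernel support vector machine (`"svm"`,
#' e1071, features standardised), a random forest (`"rf"`), a
#' single-hidden-layer neural network with softmax output (`"ann"`,
#' nnet, features standardised, max 500 iterations) and gradient-boosted
#' trees (`"xgboost"`, softmax objective). Tree-ensemble sizes default
#' to ntree = 800 / nrounds = 10 for the full feature set and the
#' reduced ntree = 20 / nrounds = 5 for simplified sets.
#'
#' @param x Numeric feature matrix or data frame (bouts by features).
#' @param y Behaviour labels (factor or character), at least 2 classes.
#' @param method One of `"lda"`, `"dt"`, `"svm"`, `"rf"`, `"ann"`,
#'   `"xgboost"`.
#' @param hyperparams Named list overriding the method defaults (e.g.
#'   `list(gamma = 0.1, cost = 10)` for SVM).
#' @param feature_set `"full"` or `"simplified"`; selects the ensemble
#'   size defaults above.
#' @param seed Integer seed; all stochastic backends are seeded so the
#'   same call reproduces the same model.
#' @return An object of class `"etho_model"` with elements `method`,
#'   `fit` (backend object), `feature_names`, `class_labels`,
#'   `hyperparams`, `scaling` (ANN only) and `lda_features` (LDA only).
#' @seealso [predict.etho_model()], [cross_validate()], [export_compact()]
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 3), 20))
#' colnames(X) <- c("f1", "f2")
#' y <- rep(c("rest", "move"), each = 20)
#' m <- etho_fit(X, y, "dt")
#' table(predict(m, X), y)
#' @export
etho_fit <- function(x, y, method = c("lda", "dt", "svm", "rf", "ann",
                                      "xgboost"),
                     hyperparams = list(), feature_set = c("full",
                                                           "simplified"),
                     seed = 1L) {
  method <- match.arg(method)
  feature_set <- match.arg(feature_set)
  X <- check_feature_matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (length(y) != nrow(X)) stop("x and y lengths differ", call. = FALSE)
  hp <- utils::modifyList(default_hyperparams(method, ncol(X), feature_set),
                          hyperparams)
  set.seed(seed)
  scaling <- NULL
  lda_features <- NULL
  fit <- switch(method,
    lda = {
      lda_features <- prune_correlated_features(X, hp$cutoff)
      MASS::lda(X[, lda_features, drop = FALSE], grouping = y)
    },
    dt = rpart::rpart(label ~ ., data = data.frame(label = y,
                                                   as.data.frame(X)),
                      method = "class",
                      control = rpart::rpart.control(cp = hp$cp)),
    # scale only non-constant columns; e1071 would otherwise disable
    # scaling altogether when any feature (e.g. a static-variance column
    # under the full-bout decomposition) is constant
    svm = e1071::svm(X, y, kernel = "radial", gamma = hp$gamma,
                     cost = hp$cost,
                     scale = apply(X, 2L, var) > 0),
    rf = randomForest::randomForest(X, y, ntree = hp$ntree,
                                    mtry = min(hp$mtry, ncol(X))),
    ann = {
      ctr <- colMeans(X)
      scl <- apply(X, 2L, sd)
      scl[scl == 0] <- 1
      scaling <- list(center = ctr, scale = scl)
      Xs <- scale(X, ctr, scl)
      nnet::nnet(Xs, nnet::class.ind(y), size = hp$size, decay = hp$decay,
                 maxit = hp$maxit, softmax = TRUE, trace = FALSE,
                 MaxNWts = 100000L)
    },
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
      xgboost::xgb.train(
        params = list(objective = "multi:softmax",
                      num_class = nlevels(y), max_depth = hp$max_depth,
                      eta = hp$eta, nthread = 1L, seed = seed),
        dtrain, nrounds = hp$nrounds)
    })
  structure(list(method = method, fit = fit,
                 feature_names = colnames(X),
                 class_labels = levels(y), hyperparams = hp,
                 feature_set = feature_set, scaling = scaling,
                 lda_features = lda_features, seed = seed),
            class = "etho_model")
}

#' @export
print.etho_model <- function(x, ...) {
  cat(sprintf("ethoclass %s model: %d features, %d classes\n",
              toupper(x$method), length(x$feature_names),
              length(x$class_labels)))
  cat("  classes:", paste(x$class_labels, collapse = ", "), "\n")
  hp <- x$hyperparams
  cat("  hyperparameters:",
      paste(names(hp), unlist(hp), sep = "=", collapse = ", "), "\n")
  if (!is.null(x$lda_features))
    cat(sprintf("  LDA retained %d of %d features after correlation pruning\n",
                length(x$lda_features), length(x$feature_names)))
  invisible(x)
}

#' @export
summary.etho_model <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Predict behaviour labels
#'
#' @param object An [etho_fit()] model.
#' @param newdata Feature matrix or data frame whose columns match the
#'   training features (any order; missing or extra columns are an
#'   error).
#' @param ... Unused.
#' @return Character vector of predicted behaviour labels.
#' @export
predict.etho_model <- function(object, newdata, ...) {
  X <- check_feature_matrix(newdata)
  fn <- object$feature_names
  missing <- setdiff(fn, colnames(X))
  extra <- setdiff(colnames(X), fn)
  if (length(missing) || length(extra))
    stop("feature columns do not match the model; missing: [",
         paste(missing, collapse = ", "), "], extra: [",
         paste(extra, collapse = ", "), "]", call. = FALSE)
  X <- X[, fn, drop = FALSE]
  out <- switch(object$method,
    lda = as.character(predict(object$fit,
                               X[, object$lda_features,
                                 drop = FALSE])$class),
    dt = as.character(predict(object$fit, as.data.frame(X),
                              type = "class")),
    svm = as.character(predict(object$fit, X)),
    rf = as.character(predict(object$fit, X)),
    ann = {
      Xs <- scale(X, object$scaling$center, object$scaling$scale)
      pr <- predict(object$fit, Xs)
      object$class_labels[apply(pr, 1L, which.max)]
    },
    xgboost = {
      cls <- predict(object$fit, xgboost::xgb.DMatrix(X))
      object$class_labels[cls + 1L]
    })
  unname(out)
}

#' Default hyperparameter search grids
#'
#' Modest per-method candidate grids for [tune_classifier()]. SVM and
#' ANN are the two methods whose accuracy depends strongly on tuning
#' (and need re-tuning whenever the feature set changes); RF and XGBoost
#' perform well at their defaults and get small grids around them.
#'
#' @param method Classifier method (see [etho_fit()]).
#' @return Named list of candidate vectors.
#' @export
default_tuning_grid <- function(method = c("lda", "dt", "svm", "rf",
                                           "ann", "xgboost")) {
  switch(match.arg(method),
         lda = list(cutoff = 0.7),
         dt = list(cp = c(0.1, 0.01, 0.001)),
         svm = list(gamma = c(0.001, 0.01, 0.1), cost = c(1, 10, 100)),
         rf = list(ntree = c(200L, 800L)),
         ann = list(size = c(5L, 10L), decay = c(0.1, 0.01)),
         xgboost = list(nrounds = c(5L, 10L)))
}

# simplicity ordering of tuning candidates, so that under accuracy ties
# the first (simplest) candidate wins
order_candidates <- function(method, cand) {
  key <- switch(method,
    dt = order(-cand$cp),
    svm = order(cand$cost, cand$gamma),
    rf = order(cand$ntree, cand$mtry),
    ann = order(cand$size, -cand$decay),
    xgboost = order(cand$nrounds),
    seq_len(nrow(cand)))
  cand[key, , drop = FALSE]
}

#' Tune classifier hyperparameters by stratified cross-validation
#'
#' Exhaustive grid search maximising mean stratified k-fold overall
#' accuracy, the tuning scheme conventionally applied to these
#' classifiers. Accuracy ties break toward the simpler model (smaller
#' tree/network/cost, stronger regularisation). All candidates are
#' evaluated on the same seeded folds.
#'
#' @param method Classifier method (see [etho_fit()]).
#' @param x,y Features and labels as in [etho_fit()].
#' @param grid Named list of candidate vectors, e.g.
#'   `list(cp = c(0.1, 0.01, 0.001))`; crossed with `expand.grid`.
#' @param k Number of folds (default 10). Every class needs at least `k`
#'   members; merge rare behaviour categories otherwise.
#' @param seed Integer seed for fold construction and fits.
#' @param feature_set Passed to [etho_fit()].
#' @return List with `best` (named list of chosen hyperparameters) and
#'   `results` (data frame of candidates and mean CV accuracy).
#' @export
tune_classifier <- function(method, x, y, grid, k = 10L, seed = 1L,
                            feature_set = c("full", "simplified")) {
  feature_set <- match.arg(feature_set)
  if (!length(grid)) stop("tuning grid is empty", call. = FALSE)
  X <- check_feature_matrix(x)
  y <- factor(y)
  cand <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  cand <- order_candidates(method, cand)
  folds <- stratified_folds(y, k = k, seed = seed)
  acc <- numeric(nrow(cand))
  for (ci in seq_len(nrow(cand))) {
    hp <- as.list(cand[ci, , drop = FALSE])
    fold_acc <- numeric(k)
    for (f in seq_len(k)) {
      tr <- folds != f
      m <- etho_fit(X[tr, , drop = FALSE], y[tr], method,
                    hyperparams = hp, feature_set = feature_set,
                    seed = seed + f)
      fold_acc[f] <- mean(predict(m, X[!tr, , drop = FALSE]) == y[!tr])
    }
    acc[ci] <- mean(fold_acc)
  }
  best <- as.list(cand[which.max(acc), , drop = FALSE])
  list(best = best,
       results = cbind(cand, cv_accuracy = acc, row.names = NULL))
}
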