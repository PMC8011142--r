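#' Stratified fold assignment
#'
#' Partitions bout indices into `k` folds in which every behaviour
#' category is proportionally represented: within each class, shuffled
#' indices are dealt so that per-class fold sizes differ by at most one,
#' with the remainder dealt to seeded-random folds.
#'
#' @param y Behaviour labels (factor or character).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, one per element of `y`.
#' @export
stratified_folds <- function(y, k = 10L, seed = 1L) {
  y <- factor(y)
  k <- as.integer(k)
  counts <- table(y)
  if (any(counts < k))
    stop("class(es) with fewer than k members: ",
         paste(names(counts)[counts < k], collapse = ", "),
         "; merge rare behaviour categories or reduce k", call. = FALSE)
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    n <- length(idx)
    assign <- c(rep(seq_len(k), n %/% k),
                if (n %% k) sample(k, n %% k))
    folds[idx] <- assign
  }
  folds
}

#' Confusion matrix over a fixed class set
#'
#' @param true,pred True and predicted behaviour labels.
#' @param labels Class label set (default: sorted union).
#' @return A square matrix of class `"confusion_matrix"`, rows = true,
#'   columns = predicted.
#' @export
confusion_matrix <- function(true, pred,
                             labels = sort(unique(c(as.character(true),
                                                    as.character(pred))))) {
  cm <- table(factor(as.character(true), levels = labels),
              factor(as.character(pred), levels = labels))
  cm <- unclass(as.matrix(cm))
  names(dimnames(cm)) <- c("true", "predicted")
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Per-class recall, precision and F1
#'
#' One-vs-rest collapse of the confusion matrix: for each behaviour,
#' recall = TP/(TP+FN), precision = TP/(TP+FP) and
#' F1 = 2 * recall * precision / (recall + precision). Whenever a
#' denominator is zero (class never true, never predicted, or no true
#' positives at all) the metric is 0.
#'
#' @param cm A [confusion_matrix()] (true x predicted).
#' @return Data frame with columns `class`, `recall`, `precision`, `f1`.
#' @export
f1_per_class <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  res <- lapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, -i])
    fp <- sum(cm[-i, i])
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    f1 <- if (recall + precision == 0) 0 else
      2 * recall * precision / (recall + precision)
    data.frame(class = rownames(cm)[i], recall = recall,
               precision = precision, f1 = f1)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Overall classification accuracy
#'
#' The fraction of bouts whose behaviour was correctly classified:
#' the confusion-matrix trace over the total count. This equals the
#' one-vs-rest (TP+TN)/(TP+TN+FP+FN) form averaged over classes when
#' collapsed per class.
#'
#' @param cm A [confusion_matrix()].
#' @return Accuracy in `[0, 1]`.
#' @export
overall_accuracy <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  sum(diag(cm)) / total
}

# mean and 95% CI over folds using Student t with k-1 df
t_ci95 <- function(v) {
  k <- length(v)
  m <- mean(v)
  half <- if (k > 1L) qt(0.975, k - 1L) * sd(v) / sqrt(k) else 0
  c(mean = m, lower = m - half, upper = m + half)
}

#' Stratified k-fold cross-validation of a behaviour classifier
#'
#' Runs the full train/validate cycle: the bouts are partitioned with
#' [stratified_folds()]; in each of the `k` runs one fold is held out
#' for validation only and the model is trained on the remaining folds.
#' Per fold, the confusion matrix, overall accuracy and per-class F1 are
#' recorded; means and 95% confidence intervals (Student t, k-1 df)
#' over folds summarise the report.
#'
#' @inheritParams etho_fit
#' @param k Number of folds (default 10).
#' @return An object of class `"cv_report"`: `fold_accuracy` (length k),
#'   `accuracy` (mean/lower/upper), `f1` (fold x class matrix),
#'   `f1_summary` (per-class mean/lower/upper), `confusion` (summed
#'   out-of-fold confusion matrix), `confusions` (per fold), `folds`
#'   (assignment vector), plus the method and hyperparameters used.
#' @export
cross_validate <- function(x, y, method, hyperparams = list(),
                           feature_set = c("full", "simplified"),
                           k = 10L, seed = 1L) {
  feature_set <- match.arg(feature_set)
  X <- check_feature_matrix(x)
  y <- factor(y)
  labels <- levels(y)
  folds <- stratified_folds(y, k = k, seed = seed)
  fold_acc <- numeric(k)
  f1_mat <- matrix(NA_real_, k, length(labels),
                   dimnames = list(NULL, labels))
  cms <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    m <- etho_fit(X[tr, , drop = FALSE], y[tr], method,
                  hyperparams = hyperparams, feature_set = feature_set,
                  seed = seed + f)
    pred <- predict(m, X[!tr, , drop = FALSE])
    cm <- confusion_matrix(y[!tr], pred, labels = labels)
    cms[[f]] <- cm
    fold_acc[f] <- overall_accuracy(cm)
    f1_mat[f, ] <- f1_per_class(cm)$f1
  }
  total_cm <- Reduce(`+`, lapply(cms, as.matrix))
  f1_summary <- t(apply(f1_mat, 2L, t_ci95))
  structure(list(method = method, k = k, seed = seed,
                 hyperparams = hyperparams, feature_set = feature_set,
                 class_labels = labels, folds = folds,
                 fold_accuracy = fold_acc, accuracy = t_ci95(fold_acc),
                 f1 = f1_mat, f1_summary = f1_summary,
                 confusion = structure(total_cm,
                                       class = c("confusion_matrix",
                                                 "matrix")),
                 confusions = cms),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Stratified %d-fold cross-validation, method: %s\n",
              x$k, toupper(x$method)))
  cat(sprintf("  overall accuracy: %.3f (95%% CI %.3f-%.3f)\n",
              x$accuracy[["mean"]], x$accuracy[["lower"]],
              x$accuracy[["upper"]]))
  cat("  per-class F1 (mean [95% CI]):\n")
  for (cl in rownames(x$f1_summary))
    cat(sprintf("    %-14s %.3f [%.3f, %.3f]\n", cl,
                x$f1_summary[cl, "mean"], x$f1_summary[cl, "lower"],
                x$f1_summary[cl, "upper"]))
  invisible(x)
}
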