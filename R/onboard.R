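# Compact on-board models
#
# The four classifiers that are practical to run on a tracker (SVM, ANN,
# RF, XGBoost) are exported to minimal parameter structures, and
# prediction is re-implemented here on plain arrays with no dependency
# on the training backend, exactly as microcontroller firmware would run
# it: RBF-kernel evaluations and one-vs-one votes for SVM, a dense
# forward pass for ANN, and tree traversal with vote counting / leaf
# score summation for the tree ensembles. All tie-breaks resolve to the
# alphabetically first class label so the engine's behaviour is fully
# specified.
#
# Tree node arrays use columns (feature, threshold, left, right, leaf):
# feature = 0 marks a leaf; for forest leaves `leaf` is a class index,
# for boosted leaves `threshold` carries the leaf score. The traversal
# rule is strictly `x < threshold` goes left; exporters convert any
# backend convention (randomForest splits on `<=`) to this rule by
# nudging thresholds to the next representable double.

# smallest representable double strictly greater than x
next_up <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) return(v)
    s <- 2^-1074
    while (v + s == v) s <- s * 2
    v + s
  }, numeric(1))
}

TREE_COLS <- c("feature", "threshold", "left", "right", "leaf")

validate_tree <- function(tree) {
  n <- nrow(tree)
  for (i in seq_len(n)) {
    if (tree[i, 1L] == 0) next            # leaf
    l <- tree[i, 3L]; r <- tree[i, 4L]
    if (l <= i || r <= i || l > n || r > n)
      stop("malformed tree: child pointer out of range or non-increasing",
           call. = FALSE)
  }
  invisible(tree)
}

#' Export a trained classifier to a compact on-board structure
#'
#' Extracts the minimal parameters needed for prediction without the
#' training software: support vectors, dual coefficients, intercepts
#' and feature scaling for SVM; dense weight matrices, biases and
#' scaling for ANN; per-tree node arrays for random forest and boosted
#' trees. The result is self-contained (feature names, class labels and
#' any scaling included), re-importable via JSON
#' ([write_compact_json()]) and consumed by the `predict_compact_*()`
#' engines. Exporting an already-compact model returns it unchanged.
#' LDA and decision-tree models are not supported on-board.
#'
#' @param model An [etho_fit()] model with method `"svm"`, `"ann"`,
#'   `"rf"` or `"xgboost"`.
#' @return An object of class `"compact_svm"`, `"compact_ann"`,
#'   `"compact_forest"` or `"compact_boost"` (all also
#'   `"compact_model"`).
#' @export
export_compact <- function(model) {
  if (inherits(model, "compact_model")) return(model)
  if (!inherits(model, "etho_model"))
    stop("export_compact needs a trained etho_model", call. = FALSE)
  switch(model$method,
         svm = export_compact_svm(model),
         rf = export_compact_forest(model),
         ann = export_compact_ann(model),
         xgboost = export_compact_boost(model),
         stop("method '", model$method,
              "' has no on-board export (only svm, ann, rf, xgboost)",
              call. = FALSE))
}

export_compact_svm <- function(model) {
  f <- model$fit
  # e1071 skips scaling for constant columns (or, if any is constant,
  # disables scaling altogether); expand to a full per-column centre/scale
  p <- length(model$feature_names)
  ctr <- numeric(p); scl <- rep(1, p)
  if (!is.null(f$x.scale)) {
    ctr[f$scaled] <- as.numeric(f$x.scale$`scaled:center`)
    scl[f$scaled] <- as.numeric(f$x.scale$`scaled:scale`)
  }
  structure(list(
    type = "svm",
    SV = unname(as.matrix(f$SV)),
    coefs = unname(as.matrix(f$coefs)),
    rho = as.numeric(f$rho),
    nSV = as.integer(f$nSV),
    x_center = ctr,
    x_scale = scl,
    gamma = f$gamma,
    class_order = f$levels[f$labels],   # internal (libsvm) class order
    class_labels = model$class_labels,
    feature_names = model$feature_names),
    class = c("compact_svm", "compact_model"))
}

export_compact_ann <- function(model) {
  f <- model$fit
  din <- f$n[1L]; dh <- f$n[2L]; dout <- f$n[3L]
  w <- f$wts
  W1 <- matrix(0, dh, din); b1 <- numeric(dh)
  idx <- 1L
  for (h in seq_len(dh)) {
    b1[h] <- w[idx]
    W1[h, ] <- w[idx + seq_len(din)]
    idx <- idx + din + 1L
  }
  W2 <- matrix(0, dout, dh); b2 <- numeric(dout)
  for (o in seq_len(dout)) {
    b2[o] <- w[idx]
    W2[o, ] <- w[idx + seq_len(dh)]
    idx <- idx + dh + 1L
  }
  structure(list(
    type = "ann", layer_sizes = as.integer(f$n),
    W1 = W1, b1 = b1, W2 = W2, b2 = b2,
    x_center = as.numeric(model$scaling$center),
    x_scale = as.numeric(model$scaling$scale),
    class_labels = model$class_labels,
    feature_names = model$feature_names),
    class = c("compact_ann", "compact_model"))
}

export_compact_forest <- function(model) {
  f <- model$fit
  trees <- lapply(seq_len(f$ntree), function(t) {
    g <- randomForest::getTree(f, t, labelVar = FALSE)
    leaf <- g[, "status"] == -1
    tree <- cbind(
      feature = ifelse(leaf, 0L, g[, "split var"]),
      threshold = ifelse(leaf, 0, next_up(g[, "split point"])),
      left = ifelse(leaf, 0L, g[, "left daughter"]),
      right = ifelse(leaf, 0L, g[, "right daughter"]),
      leaf = ifelse(leaf, g[, "prediction"], 0L))
    colnames(tree) <- TREE_COLS
    validate_tree(tree)
  })
  structure(list(
    type = "forest", trees = trees, ntree = f$ntree,
    class_labels = model$class_labels,
    feature_names = model$feature_names),
    class = c("compact_forest", "compact_model"))
}

export_compact_boost <- function(model) {
  f <- model$fit
  n_class <- length(model$class_labels)
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = f))
  fidx <- match(dt$Feature, model$feature_names)
  trees <- lapply(sort(unique(dt$Tree)), function(t) {
    td <- dt[dt$Tree == t, , drop = FALSE]
    td <- td[order(td$Node), , drop = FALSE]
    row_of <- function(id) match(id, td$ID)
    leaf <- td$Feature == "Leaf"
    tree <- cbind(
      feature = ifelse(leaf, 0L, fidx[match(td$ID, dt$ID)]),
      threshold = ifelse(leaf, td$Gain, td$Split),
      left = ifelse(leaf, 0L, row_of(td$Yes)),
      right = ifelse(leaf, 0L, row_of(td$No)),
      leaf = as.integer(leaf))
    colnames(tree) <- TREE_COLS
    validate_tree(tree)
  })
  nrounds <- length(trees) / n_class
  if (nrounds != round(nrounds))
    stop("tree count is not nrounds x n_classes", call. = FALSE)
  structure(list(
    type = "boost", trees = trees, nrounds = as.integer(nrounds),
    n_class = n_class, class_labels = model$class_labels,
    feature_names = model$feature_names),
    class = c("compact_boost", "compact_model"))
}

#' @export
print.compact_model <- function(x, ...) {
  cat(sprintf("Compact on-board %s model: %d features, %d classes\n",
              x$type, length(x$feature_names), length(x$class_labels)))
  rep <- model_storage_bytes(x)
  cat(sprintf("  storage at %d-byte values: %.3f kB\n", rep$value_bytes,
              rep$total_bytes / 1000))
  invisible(x)
}

# coerce engine input to a row matrix in the model's feature order
as_feature_matrix <- function(m, f) {
  if (is.null(dim(f))) f <- matrix(f, nrow = 1L,
                                   dimnames = list(NULL, names(f)))
  f <- as.matrix(f)
  if (!is.null(colnames(f)) && all(m$feature_names %in% colnames(f)))
    f <- f[, m$feature_names, drop = FALSE]
  if (ncol(f) != length(m$feature_names))
    stop(sprintf("feature count mismatch: model expects %d, got %d",
                 length(m$feature_names), ncol(f)), call. = FALSE)
  f
}

# among tied maxima, the alphabetically first class label wins
alpha_argmax <- function(scores, labels) {
  mx <- max(scores)
  tied <- labels[scores == mx]
  list(label = min(tied), tie = length(tied) > 1L)
}

#' Scratch prediction with a compact SVM
#'
#' The on-board RBF-SVM decision rule: the query is standardised with
#' the stored centre/scale, the RBF kernel
#' `exp(-gamma * ||f - SV||^2)` is evaluated against every support
#' vector, each unordered class pair casts a vote from the sign of its
#' decision value `sum(coef * K) - rho`, and the class with most votes
#' wins (vote ties go to the alphabetically first label).
#'
#' @param m A `"compact_svm"` from [export_compact()].
#' @param f Feature vector, or matrix with one row per bout (named
#'   columns are reordered to the model's feature order).
#' @return Character vector of class labels, with attribute `"ties"`
#'   flagging rows decided by the tie-break.
#' @export
predict_compact_svm <- function(m, f) {
  X <- as_feature_matrix(m, f)
  Xs <- sweep(sweep(X, 2L, m$x_center), 2L, m$x_scale, `/`)
  k <- length(m$nSV)
  start <- cumsum(c(1L, m$nSV))
  sv_rows <- lapply(seq_len(k), function(i)
    if (m$nSV[i] > 0L) start[i]:(start[i + 1L] - 1L) else integer(0))
  out <- character(nrow(Xs)); ties <- logical(nrow(Xs))
  for (r in seq_len(nrow(Xs))) {
    x <- Xs[r, ]
    Kv <- exp(-m$gamma * colSums((t(m$SV) - x)^2))
    votes <- numeric(k)
    p <- 0L
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      p <- p + 1L
      si <- sv_rows[[i]]
      sj <- sv_rows[[j]]
      dec <- sum(m$coefs[si, j - 1L] * Kv[si]) +
        sum(m$coefs[sj, i] * Kv[sj]) - m$rho[p]
      if (dec > 0) votes[i] <- votes[i] + 1 else votes[j] <- votes[j] + 1
    }
    a <- alpha_argmax(votes, m$class_order)
    out[r] <- a$label; ties[r] <- a$tie
  }
  structure(out, ties = ties)
}

#' Scratch prediction with a compact ANN
#'
#' Dense forward pass of the exported single-hidden-layer network:
#' standardise the query, `hidden = logistic(W1 f + b1)`,
#' `output = softmax(W2 hidden + b2)`, argmax (ties to the
#' alphabetically first label).
#'
#' @param m A `"compact_ann"` from [export_compact()].
#' @inheritParams predict_compact_svm
#' @return Character vector of class labels with attribute `"ties"`.
#' @export
predict_compact_ann <- function(m, f) {
  X <- as_feature_matrix(m, f)
  Xs <- sweep(sweep(X, 2L, m$x_center), 2L, m$x_scale, `/`)
  out <- character(nrow(Xs)); ties <- logical(nrow(Xs))
  for (r in seq_len(nrow(Xs))) {
    h <- 1 / (1 + exp(-(m$W1 %*% Xs[r, ] + m$b1)))
    z <- as.numeric(m$W2 %*% h + m$b2)
    p <- exp(z - max(z)); p <- p / sum(p)
    a <- alpha_argmax(p, m$class_labels)
    out[r] <- a$label; ties[r] <- a$tie
  }
  structure(out, ties = ties)
}

# traverse one node-array tree; returns the leaf row
traverse_tree <- function(tree, x) {
  i <- 1L
  while (tree[i, 1L] != 0) {
    i <- if (x[tree[i, 1L]] < tree[i, 2L]) tree[i, 3L] else tree[i, 4L]
  }
  i
}

#' Scratch prediction with a compact random forest
#'
#' Every tree is traversed by comparison operations only (strictly
#' `feature < threshold` goes left) down to a leaf class; the majority
#' vote over trees decides, ties going to the alphabetically first
#' label.
#'
#' @param m A `"compact_forest"` from [export_compact()].
#' @inheritParams predict_compact_svm
#' @return Character vector of class labels with attribute `"ties"`.
#' @export
predict_compact_forest <- function(m, f) {
  X <- as_feature_matrix(m, f)
  nc <- length(m$class_labels)
  out <- character(nrow(X)); ties <- logical(nrow(X))
  for (r in seq_len(nrow(X))) {
    votes <- numeric(nc)
    for (tree in m$trees) {
      cl <- tree[traverse_tree(tree, X[r, ]), 5L]
      votes[cl] <- votes[cl] + 1
    }
    a <- alpha_argmax(votes, m$class_labels)
    out[r] <- a$label; ties[r] <- a$tie
  }
  structure(out, ties = ties)
}

#' Scratch prediction with compact boosted trees
#'
#' For each class, the leaf scores of its `nrounds` trees are summed
#' (trees are stored per round per class); the class with the largest
#' summed margin wins. The softmax is omitted because it is monotone in
#' the margins and cannot change the argmax; ties go to the
#' alphabetically first label.
#'
#' @param m A `"compact_boost"` from [export_compact()].
#' @inheritParams predict_compact_svm
#' @return Character vector of class labels with attribute `"ties"`.
#' @export
predict_compact_boost <- function(m, f) {
  X <- as_feature_matrix(m, f)
  nc <- m$n_class
  if (length(m$trees) != m$nrounds * nc)
    stop("tree count is not nrounds x n_classes", call. = FALSE)
  out <- character(nrow(X)); ties <- logical(nrow(X))
  for (r in seq_len(nrow(X))) {
    margin <- numeric(nc)
    for (t in seq_along(m$trees)) {
      cl <- (t - 1L) %% nc + 1L
      tree <- m$trees[[t]]
      margin[cl] <- margin[cl] + tree[traverse_tree(tree, X[r, ]), 2L]
    }
    a <- alpha_argmax(margin, m$class_labels)
    out[r] <- a$label; ties[r] <- a$tie
  }
  structure(out, ties = ties)
}

#' @export
predict.compact_svm <- function(object, newdata, ...)
  predict_compact_svm(object, newdata)
#' @export
predict.compact_ann <- function(object, newdata, ...)
  predict_compact_ann(object, newdata)
#' @export
predict.compact_forest <- function(object, newdata, ...)
  predict_compact_forest(object, newdata)
#' @export
predict.compact_boost <- function(object, newdata, ...)
  predict_compact_boost(object, newdata)

#' Storage requirement of a compact model
#'
#' Parameter-count accounting of the on-board footprint. SVM: support
#' vector entries, dual coefficients, intercepts and the per-feature
#' centre/scale, all at `value_bytes` per value. ANN: weights, biases
#' and scaling. Tree ensembles: every node costs a feature index, a
#' threshold (or leaf score/class), and two child references, i.e.
#' 4 values per node. ANN storage thus grows with the number of
#' weights, and forest/boost storage with the total node count.
#'
#' @param m A compact model from [export_compact()].
#' @param value_bytes Width of one stored value in bytes (default 4,
#'   i.e. single-precision floats / 32-bit indices).
#' @return An object of class `"storage_report"`: named `components`
#'   (bytes), `total_bytes`, `total_kb` and `value_bytes`.
#' @export
model_storage_bytes <- function(m, value_bytes = 4L) {
  stopifnot(inherits(m, "compact_model"), value_bytes >= 1)
  comp <- switch(m$type,
    svm = c(SV = length(m$SV), coefs = length(m$coefs),
            rho = length(m$rho), scale = length(m$x_center) +
              length(m$x_scale)),
    ann = c(weights = length(m$W1) + length(m$W2),
            biases = length(m$b1) + length(m$b2),
            scale = length(m$x_center) + length(m$x_scale)),
    forest = c(tree_nodes = 4L * sum(vapply(m$trees, nrow, integer(1)))),
    boost = c(tree_nodes = 4L * sum(vapply(m$trees, nrow, integer(1)))))
  comp <- comp * value_bytes
  structure(list(type = m$type, components = comp,
                 total_bytes = sum(comp), total_kb = sum(comp) / 1000,
                 value_bytes = as.integer(value_bytes)),
            class = "storage_report")
}

#' @export
print.storage_report <- function(x, ...) {
  cat(sprintf("On-board storage (%s, %d-byte values): %.3f kB\n",
              x$type, x$value_bytes, x$total_kb))
  for (nm in names(x$components))
    cat(sprintf("  %-10s %d bytes\n", nm, x$components[[nm]]))
  invisible(x)
}

#' Raw-data to behaviour-code compression ratio
#'
#' When only the classified behaviour code leaves the tracker, each bout
#' of raw ACC samples collapses to a single label byte. For example a
#' 40-record triaxial bout at 2 bytes per value (120 ACC records x 2
#' bytes versus 1 byte) compresses 240:1.
#'
#' @param samples_per_bout ACC records per bout.
#' @param axes Number of axes (default 3).
#' @param value_bytes Bytes per stored raw value (default 2).
#' @param label_bytes Bytes per behaviour code (default 1).
#' @return The compression ratio (exact rational arithmetic at these
#'   scales).
#' @examples
#' compression_ratio(40) # 240
#' @export
compression_ratio <- function(samples_per_bout, axes = 3L,
                              value_bytes = 2L, label_bytes = 1L) {
  if (any(c(samples_per_bout, axes, value_bytes, label_bytes) <= 0))
    stop("all inputs must be positive", call. = FALSE)
  samples_per_bout * axes * value_bytes / label_bytes
}

#' Days of behaviour codes that fit in a given memory
#'
#' With one behaviour code stored per bout, a day costs
#' `label_bytes * 86400 / bout_seconds` bytes; the value is the whole
#' number of days that fit. 1 MiB at one 3.8-s bout per code holds 46
#' days of behavioural data (without timestamps).
#'
#' @param memory_bytes Available memory in bytes.
#' @param bout_seconds Bout duration in seconds.
#' @param label_bytes Bytes per behaviour code (default 1).
#' @return Integer number of whole days.
#' @examples
#' storage_days(2^20, 3.8) # 46
#' @export
storage_days <- function(memory_bytes, bout_seconds, label_bytes = 1L) {
  if (any(c(memory_bytes, bout_seconds, label_bytes) <= 0))
    stop("all inputs must be positive", call. = FALSE)
  floor(memory_bytes / (label_bytes * 86400 / bout_seconds))
}

#' Serialize a compact model to human-auditable JSON
#'
#' Full double precision is preserved, so a written-and-reread model
#' makes identical predictions.
#'
#' @param m A compact model from [export_compact()].
#' @param path Output path.
#' @return `path` invisibly (write) or the compact model (read).
#' @export
write_compact_json <- function(m, path) {
  stopifnot(inherits(m, "compact_model"))
  jsonlite::write_json(unclass(m), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_compact_json
#' @export
read_compact_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  as_mat <- function(x, cols = NULL) {
    mt <- do.call(rbind, lapply(x, function(row) unlist(row)))
    dimnames(mt) <- if (is.null(cols)) NULL else list(NULL, cols)
    mt
  }
  num <- function(x) as.numeric(unlist(x))
  chr <- function(x) as.character(unlist(x))
  m <- list(type = raw$type,
            feature_names = chr(raw$feature_names),
            class_labels = chr(raw$class_labels))
  if (m$type == "svm") {
    m <- c(m, list(SV = as_mat(raw$SV), coefs = as_mat(raw$coefs),
                   rho = num(raw$rho), nSV = as.integer(unlist(raw$nSV)),
                   x_center = num(raw$x_center),
                   x_scale = num(raw$x_scale),
                   gamma = num(raw$gamma),
                   class_order = chr(raw$class_order)))
  } else if (m$type == "ann") {
    m <- c(m, list(layer_sizes = as.integer(unlist(raw$layer_sizes)),
                   W1 = as_mat(raw$W1), b1 = num(raw$b1),
                   W2 = as_mat(raw$W2), b2 = num(raw$b2),
                   x_center = num(raw$x_center),
                   x_scale = num(raw$x_scale)))
  } else if (m$type == "forest") {
    m <- c(m, list(trees = lapply(raw$trees, as_mat, cols = TREE_COLS),
                   ntree = as.integer(unlist(raw$ntree))))
  } else if (m$type == "boost") {
    m <- c(m, list(trees = lapply(raw$trees, as_mat, cols = TREE_COLS),
                   nrounds = as.integer(unlist(raw$nrounds)),
                   n_class = as.integer(unlist(raw$n_class))))
  } else stop("unknown compact model type: ", m$type, call. = FALSE)
  cls <- switch(m$type, svm = "compact_svm", ann = "compact_ann",
                forest = "compact_forest", boost = "compact_boost")
  structure(m, class = c(cls, "compact_model"))
}
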