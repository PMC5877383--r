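#' Classifier configuration
#'
#' Four backends with the configurations typical of four-motion sEMG
#' work: kNN with 6 neighbours; a single-hidden-layer sigmoid network
#' with `n` inputs, `2n` hidden units and one output per class, trained
#' by backpropagation with weight decay; a 30-tree random forest whose
#' per-node candidate-feature count follows `s = round(log2(d))`; and an
#' RBF-kernel SVM decomposed one-versus-all. The network uses 5-fold
#' cross-validation by default (training cost), everything else 10-fold.
#'
#' @param kind `"knn"`, `"ann"`, `"rf"` or `"svm"`.
#' @param knn_k neighbours for kNN, default 6.
#' @param ann_hidden hidden units; `NULL` = `2 * n_features`.
#' @param ann_maxit,ann_decay backprop iteration cap and weight decay.
#' @param rf_trees trees in the forest, default 30.
#' @param svm_cost,svm_gamma RBF SVM parameters; `svm_gamma = NULL` means
#'   `1 / n_features`.
#' @param tune if `TRUE`, grid-search `cost`/`gamma` by inner 3-fold CV on
#'   each training fold (slower; default `FALSE` uses the fixed values).
#' @param cv_folds default folds for [crossval()]; `NULL` = 10 (5 for ann).
#' @return a `classifier_config`.
#' @export
classifier_config <- function(kind = c("svm", "knn", "rf", "ann"),
                              knn_k = 6, ann_hidden = NULL, ann_maxit = 200,
                              ann_decay = 5e-4, rf_trees = 30, svm_cost = 1,
                              svm_gamma = NULL, tune = FALSE,
                              cv_folds = NULL) {
  kind <- match.arg(kind)
  if (is.null(cv_folds)) cv_folds <- if (kind == "ann") 5 else 10
  structure(list(kind = kind, knn_k = knn_k, ann_hidden = ann_hidden,
                 ann_maxit = ann_maxit, ann_decay = ann_decay,
                 rf_trees = rf_trees, svm_cost = svm_cost,
                 svm_gamma = svm_gamma, tune = tune, cv_folds = cv_folds),
            class = "classifier_config")
}

#' Random-forest per-node feature-subset size
#'
#' The number of candidate features tried at each tree node:
#' `s = round(log2(d))`, at least 1.
#'
#' @param d total feature count (>= 2).
#' @return integer subset size.
#' @examples
#' rf_node_subset(42)  # 5
#' @export
rf_node_subset <- function(d) {
  if (d < 2) stop("d must be >= 2")
  max(1L, as.integer(round(log2(d))))
}

#' F-score from confusion counts
#'
#' `F = 2 TP / (2 TP + FP + FN)`.
#'
#' @param tp,fp,fn true-positive, false-positive and false-negative counts.
#' @return fraction in `[0, 1]`.
#' @export
f_score <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be >= 0")
  if (tp + fp + fn == 0) stop("all-zero counts")
  2 * tp / (2 * tp + fp + fn)
}

# evaluate expr under a temporary RNG seed, restoring global state after
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  expr
}

# stratified fold assignment: within each class, seeded shuffle then
# round-robin folds
make_folds <- function(labels, k, seed) {
  tab <- table(labels)
  if (any(tab < k))
    stop("class '", names(tab)[which.min(tab)], "' has fewer windows (",
         min(tab), ") than folds (", k, ")")
  fold <- integer(length(labels))
  with_seed(seed, for (cl in names(tab)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  })
  fold
}

train_predict <- function(config, x_train, y_train, x_test, seed) {
  d <- ncol(x_train)
  switch(config$kind,
    knn = {
      mu <- colMeans(x_train)
      sdv <- apply(x_train, 2, stats::sd); sdv[sdv == 0] <- 1
      tr <- scale(x_train, mu, sdv); te <- scale(x_test, mu, sdv)
      # knn breaks distance ties via the RNG; pin it for reproducibility
      as.character(with_seed(seed,
        class::knn(tr, te, factor(y_train), k = config$knn_k)))
    },
    rf = {
      mod <- with_seed(seed, randomForest::randomForest(
        x_train, factor(y_train), ntree = config$rf_trees,
        mtry = min(d, rf_node_subset(max(d, 2)))))
      as.character(stats::predict(mod, x_test))
    },
    ann = {
      hid <- config$ann_hidden %||% (2L * d)
      mu <- colMeans(x_train)
      sdv <- apply(x_train, 2, stats::sd); sdv[sdv == 0] <- 1
      tr <- scale(x_train, mu, sdv); te <- scale(x_test, mu, sdv)
      cls <- sort(unique(y_train))
      targets <- nnet::class.ind(factor(y_train, levels = cls))
      mod <- with_seed(seed, nnet::nnet(
        tr, targets, size = hid, softmax = TRUE, decay = config$ann_decay,
        maxit = config$ann_maxit, trace = FALSE,
        MaxNWts = (d + 1) * hid + (hid + 1) * length(cls) + 1))
      cls[max.col(stats::predict(mod, te))]
    },
    svm = {
      pars <- list(cost = config$svm_cost,
                   gamma = config$svm_gamma %||% (1 / d))
      if (isTRUE(config$tune))
        pars <- tune_rbf(x_train, y_train, seed)
      ova_svm(x_train, y_train, x_test, pars$cost, pars$gamma)
    })
}

# one-versus-all RBF SVM: one binary machine per class, predict the class
# with the largest decision value
ova_svm <- function(x_train, y_train, x_test, cost, gamma) {
  cls <- sort(unique(y_train))
  dec <- vapply(cls, function(k) {
    y <- factor(ifelse(y_train == k, "pos", "rest"), levels = c("pos", "rest"))
    mod <- e1071::svm(x_train, y, kernel = "radial", cost = cost,
                      gamma = gamma, scale = TRUE)
    dvm <- attr(stats::predict(mod, x_test, decision.values = TRUE),
                "decision.values")
    if (grepl("^pos/", colnames(dvm)[1])) dvm[, 1] else -dvm[, 1]
  }, numeric(nrow(x_test)))
  if (is.null(dim(dec))) dec <- matrix(dec, nrow = 1)
  cls[max.col(dec)]
}

# small log-grid search for RBF (cost, gamma) by inner 3-fold CV
tune_rbf <- function(x, y, seed) {
  d <- ncol(x)
  grid <- expand.grid(cost = c(0.1, 1, 10), gamma = c(0.1, 1, 10) / d)
  fold <- make_folds(y, 3, seed)
  best <- NULL; best_acc <- -1
  for (g in seq_len(nrow(grid))) {
    correct <- 0
    for (f in 1:3) {
      pr <- ova_svm(x[fold != f, , drop = FALSE], y[fold != f],
                    x[fold == f, , drop = FALSE],
                    grid$cost[g], grid$gamma[g])
      correct <- correct + sum(pr == y[fold == f])
    }
    if (correct > best_acc) { best_acc <- correct; best <- grid[g, ] }
  }
  list(cost = best$cost, gamma = best$gamma)
}

#' Stratified cross-validated classification
#'
#' Splits windows into stratified folds, trains the configured classifier
#' on each training partition and predicts the held-out fold, then
#' aggregates overall accuracy, macro-averaged F-score and a row-normalized
#' confusion matrix. Deterministic for a fixed `seed`.
#'
#' @param fm a [feature_matrix()].
#' @param config a [classifier_config()].
#' @param seed seed for fold assignment and stochastic backends.
#' @param folds number of folds; default from `config`.
#' @return a `classifier_result`: `accuracy` (percent), `f_score` (macro,
#'   0-1), `confusion` (rows = true class, percentages summing to 100),
#'   `per_class_f`, `predictions`, `folds`, `seed`.
#' @export
crossval <- function(fm, config = classifier_config("svm"), seed = 1,
                     folds = NULL) {
  stopifnot(inherits(fm, "feature_matrix"),
            inherits(config, "classifier_config"))
  folds <- folds %||% config$cv_folds
  labels <- fm$labels
  fold <- make_folds(labels, folds, seed)
  pred <- character(length(labels))
  for (f in seq_len(folds)) {
    te <- fold == f
    pred[te] <- train_predict(config, fm$values[!te, , drop = FALSE],
                              labels[!te], fm$values[te, , drop = FALSE],
                              seed = seed * 1000L + f)
  }
  cls <- sort(unique(labels))
  conf_counts <- table(factor(labels, cls), factor(pred, cls))
  confusion <- sweep(conf_counts, 1, rowSums(conf_counts), "/") * 100
  per_class_f <- vapply(cls, function(k) {
    tp <- sum(pred == k & labels == k)
    f_score(tp, sum(pred == k & labels != k), sum(pred != k & labels == k))
  }, numeric(1))
  structure(list(accuracy = 100 * mean(pred == labels),
                 f_score = mean(per_class_f),
                 confusion = unclass(confusion), per_class_f = per_class_f,
                 predictions = pred, fold = fold, folds = folds,
                 seed = seed, config = config),
            class = "classifier_result")
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf("<classifier_result> %s, %d-fold CV: accuracy %.2f%%, macro F %.4f\n",
              x$config$kind, x$folds, x$accuracy, x$f_score))
  cat("confusion (row %):\n")
  print(round(x$confusion, 1))
  invisible(x)
}

#' Window-length comparison study
#'
#' Repeats the extract -> select -> classify pipeline at several analysis
#' window lengths on the same annotated recording and tabulates the
#' cross-validated accuracy of each, the standard check that shorter
#' real-time windows do not degrade recognition.
#'
#' @param rec an annotated, preprocessed [recording()].
#' @param lengths_ms analysis window lengths in ms, default
#'   `c(125, 250, 500)`.
#' @param spec a [feature_spec()].
#' @param subset_size features kept by the separability ranking, default 23.
#' @param select `"fd"`, `"ec"` or `"none"`.
#' @param config a [classifier_config()]; default 30-tree random forest.
#' @param folds,seed cross-validation folds and seed.
#' @return data.frame with `window_ms`, `n_windows`, `accuracy`, `f_score`.
#' @export
window_length_study <- function(rec, lengths_ms = c(125, 250, 500),
                                spec = feature_spec(), subset_size = 23,
                                select = c("fd", "ec", "none"),
                                config = classifier_config("rf"),
                                folds = 10, seed = 1) {
  select <- match.arg(select)
  rows <- lapply(lengths_ms, function(ms) {
    wins <- segment_recording(rec, window_spec(ms / 1000))
    fm <- extract_features(wins, rec$fs, spec)
    if (select != "none") {
      rep <- if (select == "fd") fd_score(fm) else ec_score(fm)
      fm <- fm[, rep$order[seq_len(min(subset_size, ncol(fm$values)))]]
    }
    res <- crossval(fm, config, seed = seed, folds = folds)
    data.frame(window_ms = ms, n_windows = length(wins),
               accuracy = res$accuracy, f_score = res$f_score)
  })
  do.call(rbind, rows)
}
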