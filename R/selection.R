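#' Variance-entropy separability criterion
#'
#' For each feature, the per-class variances are normalized to sum to one
#' and their Shannon entropy is taken (`0 * ln 0 := 0`). A feature whose
#' variance differs strongly between classes has low entropy and carries
#' class information; equal variances give the maximum `ln(n_classes)`.
#' Features are therefore ranked ascending (smaller value = more
#' separable).
#'
#' @param fm a [feature_matrix()] with >= 2 classes and >= 2 windows per
#'   class.
#' @param subject,channel optional provenance tags carried into the report
#'   (used by [aggregate_selection()]).
#' @return a `separability_report` with elements `method`, `sv` (named),
#'   `order` (feature names, best first), `n_classes`.
#' @export
ec_score <- function(fm, subject = NA, channel = NA) {
  stopifnot(inherits(fm, "feature_matrix"))
  cls <- unique(fm$labels)
  if (length(cls) < 2) stop("need at least 2 classes")
  if (any(table(fm$labels) < 2)) stop("every class needs >= 2 windows")
  J <- apply(fm$values, 2, function(col) {
    v <- vapply(cls, function(k) stats::var(col[fm$labels == k]), numeric(1))
    tot <- sum(v)
    if (tot == 0) return(log(length(cls)))   # no variance anywhere: no info
    V <- v / tot
    -sum(ifelse(V > 0, V * log(V), 0))
  })
  new_separability_report("EC", J, rank_order(J, decreasing = FALSE),
                          length(cls), subject, channel)
}

# mean squared difference over all |a|*|b| ordered cross pairs
d2_cross <- function(a, b) mean(a^2) - 2 * mean(a) * mean(b) + mean(b^2)

# mean squared difference over all distinct unordered within pairs;
# sum_{i<j}(a_i - a_j)^2 / C(m,2) collapses to twice the sample variance
d2_within <- function(a) {
  if (length(a) < 2) stop("need >= 2 samples for within-class distances")
  2 * stats::var(a)
}

#' Euclidean Fisher-discrimination separability criterion
#'
#' For each feature, the ratio of the mean squared between-class distance
#' (over all cross pairs of trials) to the sum of the mean squared
#' within-class distances (over all distinct pairs):
#' `J = D2(a,b) / (D2(a,a) + D2(b,b))`. Multi-class problems are split
#' one-versus-all and the binary ratios averaged. Larger J = more
#' separable; features are ranked descending. Classes with zero
#' within-class spread give an infinite ratio, which is kept as an `Inf`
#' sentinel (ranked first) with a warning.
#'
#' @inheritParams ec_score
#' @return a `separability_report`.
#' @export
fd_score <- function(fm, subject = NA, channel = NA) {
  stopifnot(inherits(fm, "feature_matrix"))
  cls <- unique(fm$labels)
  if (length(cls) < 2) stop("need at least 2 classes")
  if (any(table(fm$labels) < 2)) stop("every class needs >= 2 windows")
  J <- apply(fm$values, 2, function(col) {
    ratios <- vapply(cls, function(k) {
      a <- col[fm$labels == k]
      b <- col[fm$labels != k]
      wc <- d2_within(a) + d2_within(b)
      if (wc == 0) Inf else d2_cross(a, b) / wc
    }, numeric(1))
    mean(ratios)
  })
  if (any(is.infinite(J)))
    warning("zero within-class spread for: ",
            paste(names(J)[is.infinite(J)], collapse = ", "),
            " (infinite separability sentinel)")
  new_separability_report("FD", J, rank_order(J, decreasing = TRUE),
                          length(cls), subject, channel)
}

#' SVM recursive feature elimination ranking
#'
#' Iteratively trains a linear-kernel SVM (one binary machine per class,
#' one-versus-all, on standardized features), scores each remaining
#' feature by the loss of the squared-weight margin criterion when its
#' component is removed from the weight vector -- which reduces to the
#' squared weight `w_i^2` summed over the machines -- and eliminates the
#' lowest-scoring feature until one remains. The elimination order read
#' backwards is the rank (last eliminated = rank 1). A linear kernel is
#' used here even when final classification is RBF, since the weight
#' vector is only explicit for linear machines.
#'
#' @param fm a [feature_matrix()] with >= 2 classes.
#' @param cost SVM cost parameter, default 1.
#' @inheritParams ec_score
#' @return a `separability_report`; `sv` holds the rank (1 = best).
#' @export
rfe_rank <- function(fm, cost = 1, subject = NA, channel = NA) {
  stopifnot(inherits(fm, "feature_matrix"))
  cls <- sort(unique(fm$labels))
  if (length(cls) < 2) stop("need at least 2 classes")
  X <- scale(fm$values)
  X[, attr(X, "scaled:scale") == 0] <- 0    # constant features carry no weight
  d <- ncol(X)
  remaining <- seq_len(d)
  elim <- integer(0)
  while (length(remaining) > 1) {
    crit <- numeric(length(remaining))
    for (k in cls) {
      y <- factor(ifelse(fm$labels == k, "pos", "rest"))
      if (length(unique(y)) < 2) next
      mod <- tryCatch(
        e1071::svm(X[, remaining, drop = FALSE], y, kernel = "linear",
                   cost = cost, scale = FALSE),
        error = function(e) stop("SVM training failure: ", conditionMessage(e)))
      w <- as.numeric(crossprod(mod$coefs, mod$SV))
      crit <- crit + w^2
    }
    drop_i <- which.min(crit)               # ties: first (canonical) index
    elim <- c(elim, remaining[drop_i])
    remaining <- remaining[-drop_i]
  }
  elim <- c(elim, remaining)
  rank <- integer(d)
  rank[rev(elim)] <- seq_len(d)
  names(rank) <- colnames(fm$values)
  new_separability_report("RFE", rank, colnames(fm$values)[rev(elim)],
                          length(cls), subject, channel)
}

new_separability_report <- function(method, sv, order, n_classes,
                                    subject = NA, channel = NA) {
  structure(list(method = method, sv = sv, order = order,
                 n_classes = n_classes, subject = subject, channel = channel),
            class = "separability_report")
}

# stable rank order by value then canonical (input) position
rank_order <- function(J, decreasing) {
  key <- if (decreasing) -J else J
  names(J)[order(key, seq_along(J))]
}

#' @export
print.separability_report <- function(x, ...) {
  cat("<separability_report> method ", x$method, ", ", length(x$sv),
      " features, ", x$n_classes, " classes\n", sep = "")
  cat("  top:", paste(utils::head(x$order, 8), collapse = ", "), "...\n")
  invisible(x)
}

#' Optimal-feature-number sweep
#'
#' Walks down a separability ranking, evaluating cross-validated
#' classification accuracy for the top-1, top-2, ..., top-d feature
#' subsets. The optimal feature number (OFN) is the subset size with
#' maximum accuracy; ties resolve to the smallest subset.
#'
#' @param fm a [feature_matrix()].
#' @param report a `separability_report` covering all features of `fm`.
#' @param config a [classifier_config()]; default RBF SVM.
#' @param k_folds cross-validation folds, default 10.
#' @param seed fold-assignment seed.
#' @param sizes subset sizes to evaluate (default `1:d`).
#' @return a `selection_result` with `selected`, `ofn`, `accuracy_curve`.
#' @export
ofn_sweep <- function(fm, report, config = classifier_config("svm"),
                      k_folds = 10, seed = 1, sizes = NULL) {
  stopifnot(inherits(fm, "feature_matrix"),
            inherits(report, "separability_report"))
  if (!all(report$order %in% colnames(fm$values)))
    stop("report does not cover the feature matrix")
  d <- ncol(fm$values)
  if (is.null(sizes)) sizes <- seq_len(d)
  acc <- vapply(sizes, function(s) {
    sub <- fm[, report$order[seq_len(s)]]
    crossval(sub, config, seed = seed, folds = k_folds)$accuracy
  }, numeric(1))
  names(acc) <- sizes
  ofn <- sizes[which.max(acc)]
  structure(list(method = report$method, selected = report$order[seq_len(ofn)],
                 ofn = ofn, accuracy_curve = acc),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> method ", x$method %||% "?", "\n", sep = "")
  if (!is.null(x$ofn))
    cat("  OFN = ", x$ofn, " (accuracy ",
        round(max(x$accuracy_curve), 2), "%)\n", sep = "")
  cat("  selected:", paste(utils::head(x$selected, 10), collapse = ", "),
      if (length(x$selected) > 10) "..." else "", "\n")
  invisible(x)
}

#' Aggregate separability reports across subjects and channels
#'
#' For the value-based criteria (EC, FD) each report's separability values
#' are min-max normalized to `[0, 1]`, averaged across subjects within
#' each channel, and summed across channels; the top `subset_size`
#' features by the method's rank direction are selected. For RFE the
#' number of times each feature appears in a report's top `subset_size`
#' is counted (so with S subjects and C channels the maximum possible
#' frequency is `S * C`) and features are sorted by descending frequency.
#' Ties break by canonical feature order.
#'
#' @param reports list of `separability_report`s (same feature set; their
#'   `subject`/`channel` tags drive the grouping).
#' @param subset_size number of features to select.
#' @return a `selection_result` with `selected` and either `aggregate_sv`
#'   or `frequency`.
#' @export
aggregate_selection <- function(reports, subset_size) {
  if (!length(reports)) stop("no reports")
  method <- reports[[1]]$method
  feats <- names(reports[[1]]$sv)
  for (r in reports) {
    if (!identical(r$method, method)) stop("mixed methods in reports")
    if (!setequal(names(r$sv), feats)) stop("inconsistent feature name sets")
  }
  if (method == "RFE") {
    freq <- setNames(numeric(length(feats)), feats)
    for (r in reports) {
      top <- r$order[seq_len(min(subset_size, length(r$order)))]
      freq[top] <- freq[top] + 1
    }
    ord <- order(-freq, seq_along(feats))
    return(structure(list(method = method,
                          selected = feats[ord][seq_len(subset_size)],
                          frequency = freq[ord], n_reports = length(reports)),
                     class = "selection_result"))
  }
  norm01 <- function(v) {
    v[is.infinite(v)] <- max(v[is.finite(v)], 0)
    rng <- range(v)
    if (diff(rng) == 0) return(v * 0)
    (v - rng[1]) / diff(rng)
  }
  channels <- unique(vapply(reports, function(r) as.character(r$channel),
                            character(1)))
  agg <- setNames(numeric(length(feats)), feats)
  for (ch in channels) {
    in_ch <- Filter(function(r) identical(as.character(r$channel), ch), reports)
    per_subj <- vapply(in_ch, function(r) norm01(r$sv[feats]),
                       numeric(length(feats)))
    agg <- agg + rowMeans(as.matrix(per_subj))
  }
  ord <- if (method == "EC") order(agg, seq_along(feats))
         else order(-agg, seq_along(feats))
  structure(list(method = method, selected = feats[ord][seq_len(subset_size)],
                 aggregate_sv = agg[ord], n_reports = length(reports)),
            class = "selection_result")
}

#' Rank channels by single-channel classification accuracy
#'
#' For every channel, all `choose(n_classes, 2)` binary class-pair
#' problems are cross-validated using the channel's full feature bank; the
#' channels are ordered by the mean pairwise accuracy (ties keep input
#' order) and the top `n_top` are returned as the selected montage.
#'
#' @param channel_fms named list of single-channel [feature_matrix()]
#'   objects, one per channel, same windows/labels.
#' @param config a [classifier_config()]; default RBF SVM.
#' @param k_folds cross-validation folds, default 10.
#' @param seed fold-assignment seed.
#' @param n_top how many channels to select, default 2.
#' @return list with `ranking` (data.frame of pairwise and mean accuracies,
#'   ordered best first) and `top` (selected channel names).
#' @export
rank_channels <- function(channel_fms, config = classifier_config("svm"),
                          k_folds = 10, seed = 1, n_top = 2) {
  if (length(channel_fms) < 2) stop("need >= 2 channels")
  cls <- sort(unique(channel_fms[[1]]$labels))
  for (nm in names(channel_fms))
    if (!setequal(unique(channel_fms[[nm]]$labels), cls))
      stop("channel ", nm, " is missing a class")
  pairs <- utils::combn(cls, 2, simplify = FALSE)
  rows <- lapply(names(channel_fms), function(nm) {
    fm <- channel_fms[[nm]]
    acc <- vapply(pairs, function(p) {
      sub <- fm[fm$labels %in% p, ]
      crossval(sub, config, seed = seed, folds = k_folds)$accuracy
    }, numeric(1))
    c(acc, mean = mean(acc))
  })
  tab <- do.call(rbind, rows)
  colnames(tab) <- c(vapply(pairs, paste, character(1), collapse = "_vs_"),
                     "mean")
  df <- data.frame(channel = names(channel_fms), tab, check.names = FALSE)
  ord <- order(-df$mean, seq_len(nrow(df)))
  df <- df[ord, ]
  rownames(df) <- NULL
  list(ranking = df, top = df$channel[seq_len(min(n_top, nrow(df)))])
}
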