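#' Confusion matrix with predictions in rows
#'
#' Tabulates predictions against ground truth in the layout all reports in
#' this package use: rows are predicted classes, columns are actual classes,
#' both in the supplied class order.
#'
#' @param predicted,actual Character vectors of equal length.
#' @param classes Ordered class list; defaults to the sorted union.
#' @return Integer M x M matrix with dimnames `predicted` x `actual`.
#' @export
confusion_matrix <- function(predicted, actual, classes = NULL) {
  if (length(predicted) != length(actual)) {
    stop("predicted and actual differ in length", call. = FALSE)
  }
  if (is.null(classes)) classes <- sort(unique(c(predicted, actual)))
  cm <- table(factor(predicted, levels = classes),
              factor(actual, levels = classes))
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(predicted = classes, actual = classes))
  m
}

#' Accuracy and macro precision/recall/F from a confusion matrix
#'
#' Per-class one-vs-rest metrics from a matrix with predicted classes in
#' rows and actual classes in columns: precision is the diagonal over the
#' row sum (of everything predicted as the class, how much was right),
#' recall the diagonal over the column sum, and F their harmonic mean
#' (0 whenever either is 0). Macro values are unweighted means over
#' classes, deliberately insensitive to class imbalance. A class never
#' predicted has undefined precision; it is set to 0 with a warning.
#'
#' @param cm Square numeric matrix, rows = predicted, columns = actual.
#' @return A `"cbce_metrics"` list: `accuracy`, `per_class` (data frame with
#'   precision, recall, f), `macro_precision`, `macro_recall`, `macro_f`,
#'   `total`.
#' @export
metrics_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square",
                                 call. = FALSE)
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(cm)
  pred_n <- rowSums(cm)
  act_n <- colSums(cm)
  never <- pred_n == 0
  if (any(never)) {
    warning("class(es) never predicted; precision set to 0: ",
            paste(rownames(cm)[never], collapse = ", "), call. = FALSE)
  }
  precision <- ifelse(never, 0, tp / pred_n)
  recall <- ifelse(act_n == 0, 0, tp / act_n)
  f <- ifelse(precision + recall == 0, 0,
              2 * precision * recall / (precision + recall))
  per_class <- data.frame(class = rownames(cm) %||% as.character(seq_len(nrow(cm))),
                          precision = unname(precision),
                          recall = unname(recall), f = unname(f))
  structure(
    list(accuracy = sum(tp) / total, per_class = per_class,
         macro_precision = mean(precision), macro_recall = mean(recall),
         macro_f = mean(f), total = total),
    class = "cbce_metrics"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cbce_metrics <- function(x, ...) {
  cat(sprintf("Accuracy: %.1f%% (%d instances)\n", 100 * x$accuracy, x$total))
  cat(sprintf("Macro precision %.1f%%, recall %.1f%%, F-measure %.1f%%\n",
              100 * x$macro_precision, 100 * x$macro_recall, 100 * x$macro_f))
  invisible(x)
}

#' Stratified k-fold cross-validation of the ensemble
#'
#' Splits the instances into `folds` stratified folds (preserving class
#' proportions as far as integer counts allow), trains an ensemble on each
#' training split and predicts the held-out fold. Both accuracy summaries
#' in circulation are reported: the mean of the per-fold accuracies and the
#' pooled-confusion-matrix accuracy (trace over total); with equal fold
#' sizes they coincide up to rounding.
#'
#' @param dm A `"cbce_matrix"`.
#' @param folds Number of folds (default 5).
#' @param seed Master seed driving fold assignment and every training run.
#' @param K,cluster_mult,centroid_mode Passed to [cbce()].
#' @return A `"cbce_cv"` list: `confusion` (pooled, predicted x actual),
#'   `metrics` (from the pooled matrix), `fold_accuracy`, `mean_accuracy`,
#'   `fold` (assignment per instance), `seed`.
#' @export
cross_validate <- function(dm, folds = 5L, seed, K = 30L, cluster_mult = 3,
                           centroid_mode = NULL) {
  stopifnot(inherits(dm, "cbce_matrix"))
  folds <- as.integer(folds)
  N <- nrow(dm$x)
  if (N < folds) stop("fewer instances than folds", call. = FALSE)
  if (missing(seed) || is.null(seed)) {
    stop("an integer seed is required", call. = FALSE)
  }
  seeds <- derive_seeds(seed, folds + 1L)
  fold <- make_folds(dm$labels, folds, seeds[folds + 1L])
  predicted <- character(N)
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    test_idx <- which(fold == f)
    train <- dm[-test_idx]
    fit <- cbce(train, K = K, cluster_mult = cluster_mult,
                centroid_mode = centroid_mode, seed = seeds[f])
    predicted[test_idx] <- predict(fit, dm[test_idx])
    fold_acc[f] <- mean(predicted[test_idx] == dm$labels[test_idx])
  }
  cm <- confusion_matrix(predicted, dm$labels, dm$classes)
  structure(
    list(confusion = cm, metrics = metrics_from_confusion(cm),
         fold_accuracy = fold_acc, mean_accuracy = mean(fold_acc),
         fold = fold, seed = as.integer(seed)),
    class = "cbce_cv"
  )
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin into folds. Falls back to a plain shuffled split (with a
# warning) when some class has fewer members than folds.
make_folds <- function(labels, folds, seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  N <- length(labels)
  fold <- integer(N)
  counts <- table(labels)
  if (any(counts < folds)) {
    warning("class(es) with fewer members than folds; ",
            "using a non-stratified split", call. = FALSE)
    fold <- rep_len(seq_len(folds), N)[sample.int(N)]
    return(fold)
  }
  for (cls in names(counts)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' @export
print.cbce_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", length(x$fold_accuracy),
              x$seed))
  cat(sprintf("  mean over folds: %.1f%%  pooled: %.1f%%\n",
              100 * x$mean_accuracy, 100 * x$metrics$accuracy))
  invisible(x)
}

#' Davies-Bouldin cluster-validity index
#'
#' Scores a grouping of instances (here typically: instances grouped by
#' their activity class) by combining within-group scatter and between-
#' group separation: with per-group centroid `c_i` and scatter `s_i` (mean
#' member-to-centroid Euclidean distance), the index is the mean over
#' groups of `max_{j != i} (s_i + s_j) / d(c_i, c_j)`. Lower means
#' better-separated, tighter groups.
#'
#' @param x Numeric matrix of instances, or a `"cbce_matrix"` (its class
#'   labels then provide the default grouping).
#' @param groups Group label per row; defaults to the class labels when `x`
#'   is a `"cbce_matrix"`.
#' @return The index (positive scalar), with attribute `per_group`.
#' @export
davies_bouldin <- function(x, groups = NULL) {
  if (inherits(x, "cbce_matrix")) {
    if (is.null(groups)) groups <- x$labels
    x <- x$x
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(groups)) stop("group labels are required", call. = FALSE)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(x))
  lev <- unique(groups)
  g <- length(lev)
  if (g < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) == 0L)) stop("empty group", call. = FALSE)
  centroids <- t(vapply(lev, function(l) colMeans(x[groups == l, , drop = FALSE]),
                        numeric(ncol(x))))
  scatter <- vapply(seq_len(g), function(i) {
    mem <- x[groups == lev[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(mem, 2L, centroids[i, ])^2)))
  }, numeric(1))
  dc <- as.matrix(stats::dist(centroids))
  if (any(dc[upper.tri(dc)] == 0)) {
    stop("coincident group centroids: index undefined", call. = FALSE)
  }
  r <- vapply(seq_len(g), function(i) {
    max(vapply(setdiff(seq_len(g), i),
               function(j) (scatter[i] + scatter[j]) / dc[i, j], numeric(1)))
  }, numeric(1))
  structure(mean(r), per_group = stats::setNames(r, lev))
}

#' Ensemble-size stability experiment
#'
#' How reproducible is the accuracy of a freshly trained ensemble? For each
#' candidate ensemble size `K`, the model is retrained `repetitions` times
#' with fresh sub-seeds on a fixed stratified train/test split and the
#' standard deviation of the test accuracies is reported. Small ensembles
#' inherit the full variance of a single random subset/cluster-count draw;
#' the deviation shrinks as `K` grows, which is the basis for the default
#' `K = 30`.
#'
#' @param dm A `"cbce_matrix"`.
#' @param k_values Ensemble sizes to probe.
#' @param repetitions Training repetitions per size (default 50).
#' @param seed Master seed (drives the split and all repetitions).
#' @param test_fraction Held-out fraction of each class (default 0.3).
#' @param cluster_mult,centroid_mode Passed to [cbce()].
#' @return Data frame with columns `K`, `mean_accuracy`, `sd_accuracy`.
#' @export
stability_experiment <- function(dm, k_values = c(1L, 10L, 20L, 30L),
                                 repetitions = 50L, seed,
                                 test_fraction = 0.3, cluster_mult = 3,
                                 centroid_mode = NULL) {
  stopifnot(inherits(dm, "cbce_matrix"))
  if (missing(seed) || is.null(seed)) {
    stop("an integer seed is required", call. = FALSE)
  }
  seeds <- derive_seeds(seed, length(k_values) * repetitions + 1L)
  split_seed <- seeds[length(seeds)]
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(split_seed)
  test_idx <- unlist(lapply(unique(dm$labels), function(cls) {
    idx <- which(dm$labels == cls)
    n_test <- max(1L, round(length(idx) * test_fraction))
    sample(idx, n_test)
  }))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  train <- dm[-test_idx]
  test <- dm[test_idx]
  out <- lapply(seq_along(k_values), function(i) {
    acc <- vapply(seq_len(repetitions), function(r) {
      s <- seeds[(i - 1L) * repetitions + r]
      fit <- cbce(train, K = k_values[i], cluster_mult = cluster_mult,
                  centroid_mode = centroid_mode, seed = s)
      mean(predict(fit, test) == test$labels)
    }, numeric(1))
    data.frame(K = k_values[i], mean_accuracy = mean(acc),
               sd_accuracy = stats::sd(acc))
  })
  do.call(rbind, out)
}
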