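#' Train one base classifier
#'
#' A base classifier is one cluster collection plus its support matrix:
#' a feature subset and a cluster count are drawn at random, the training
#' set is clustered by [subspace_kmeans()] over that subset, and
#' [compute_support_matrix()] scores the retained clusters. All randomness
#' comes from the RNG state on entry (the ensemble trainer seeds it per
#' classifier).
#'
#' @param dm Training `"cbce_matrix"`.
#' @param k Index of the classifier within the ensemble (recorded).
#' @param cluster_mult Upper-bound multiplier for the cluster count draw.
#' @param centroid_mode `"mean"` or `"mode"` (see [subspace_kmeans()]).
#' @return A `"base_classifier"`: list with `k`, `subset`, `subset_raw`,
#'   `P` (requested cluster count), `clusters`, `support` (rows matching
#'   retained clusters 1:1), `dropped`.
#' @export
train_base_classifier <- function(dm, k = 1L, cluster_mult = 3,
                                  centroid_mode = c("mode", "mean")) {
  stopifnot(inherits(dm, "cbce_matrix"))
  centroid_mode <- match.arg(centroid_mode)
  N <- nrow(dm$x)
  M <- length(dm$classes)
  if (N < M) {
    stop("need at least as many training instances as classes", call. = FALSE)
  }
  subset <- sample_feature_subset(ncol(dm$x))
  P <- sample_cluster_count(M, cluster_mult)
  P <- min(P, N)  # cannot seed more centroids than instances
  collection <- subspace_kmeans(dm, subset, P, centroid_mode)
  support <- compute_support_matrix(collection, M)
  structure(
    list(k = as.integer(k), subset = collection$subset,
         subset_raw = collection$subset_raw, P = P,
         clusters = collection$clusters, support = support,
         dropped = collection$dropped, iterations = collection$iterations),
    class = "base_classifier"
  )
}

#' Train a cluster-based classifier ensemble
#'
#' Repeats the base-classifier construction `K` times, each repetition with
#' its own random feature subset and cluster count, to produce the ensemble
#' used by [predict.cbce()]. Diversity comes entirely from this
#' randomisation; the per-classifier parameters are never tuned. Each
#' classifier draws from its own sub-seed derived from `seed`, so the whole
#' model is reproducible bit for bit.
#'
#' @param dm Training `"cbce_matrix"`.
#' @param K Ensemble size (default 30, large enough in practice to make the
#'   accuracy of repeated trainings stable; see [stability_experiment()]).
#' @param cluster_mult Cluster-count upper-bound multiplier (default 3 times
#'   the number of classes).
#' @param centroid_mode `"mode"` or `"mean"`; default `NULL` picks `"mode"`
#'   for binary-encoded data and `"mean"` for numeric.
#' @param seed Integer master seed (required: training is randomised and
#'   silent nondeterminism is a bug factory).
#' @return A `"cbce"` model: list with `classifiers`, `classes`, `encoding`,
#'   `inventory`, `majority_class` (training fallback), `seed`, `K`,
#'   `cluster_mult`, `centroid_mode`.
#' @examples
#' cfg <- default_smarthome_config(n = 60)
#' dm <- encode_instances(generate_instances(cfg, seed = 7),
#'                        kasteren_inventory(), "binary")
#' fit <- cbce(dm, K = 5, seed = 1)
#' predict(fit, dm)[1:5]
#' @export
cbce <- function(dm, K = 30L, cluster_mult = 3, centroid_mode = NULL,
                 seed) {
  stopifnot(inherits(dm, "cbce_matrix"))
  K <- as.integer(K)
  if (K < 1L) stop("ensemble size K must be at least 1", call. = FALSE)
  if (length(dm$classes) < 1L) {
    stop("training data carries no class labels", call. = FALSE)
  }
  if (missing(seed) || is.null(seed)) {
    stop("an integer seed is required to train", call. = FALSE)
  }
  if (is.null(centroid_mode)) {
    centroid_mode <- if (dm$encoding == "binary") "mode" else "mean"
  }
  sub_seeds <- derive_seeds(seed, K)
  classifiers <- lapply(seq_len(K), function(k) {
    set.seed(sub_seeds[k])
    bc <- train_base_classifier(dm, k, cluster_mult, centroid_mode)
    bc$seed <- sub_seeds[k]
    bc
  })
  tab <- table(factor(dm$labels, levels = dm$classes))
  majority <- dm$classes[which.max(tab)]
  structure(
    list(classifiers = classifiers, classes = dm$classes,
         encoding = dm$encoding, inventory = dm$inventory,
         majority_class = majority, seed = as.integer(seed), K = K,
         cluster_mult = cluster_mult, centroid_mode = centroid_mode),
    class = "cbce"
  )
}

# Deterministic stream of sub-seeds below 2^31, decorrelated from the master
# seed by drawing through the seeded RNG rather than by arithmetic on it.
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}

#' @export
print.cbce <- function(x, ...) {
  cat("Cluster-based classifier ensemble\n",
      "  K = ", x$K, " base classifiers, ", length(x$classes), " classes, ",
      length(x$inventory), " sensors (", x$encoding, " encoding)\n",
      "  centroids: ", x$centroid_mode, "; seed ", x$seed, "\n", sep = "")
  sizes <- vapply(x$classifiers, function(b) length(b$clusters), integer(1))
  cat("  clusters per classifier: ", paste(sizes, collapse = " "), "\n",
      sep = "")
  invisible(x)
}
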