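#' Draw a random feature subset
#'
#' The subset size is uniform on 1..L and the positions are then drawn
#' uniformly with replacement, so smaller effective subsets than the drawn
#' size are possible. Duplicated positions are collapsed before clustering —
#' repeating a dimension would silently double-weight it in the metric — but
#' the raw draw is kept for the record.
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param L Total number of features (>= 1).
#' @return A `"feature_subset"`: list with `idx` (sorted unique 1-based
#'   positions) and `raw` (the draw before deduplication).
#' @export
sample_feature_subset <- function(L) {
  stopifnot(L >= 1L)
  l <- sample.int(L, 1L)
  raw <- sample.int(L, l, replace = TRUE)
  structure(list(idx = sort(unique(raw)), raw = raw),
            class = "feature_subset")
}

#' Draw a random cluster count
#'
#' Uniform on the inclusive range from the number of classes `M` to
#' `mult * M`. The lower bound guarantees at least one cluster per class is
#' possible; the upper bound limits (but cannot eliminate) empty clusters.
#'
#' @param M Number of classes (>= 1).
#' @param mult Upper-bound multiplier (default 3).
#' @return Integer in `[M, mult * M]`.
#' @export
sample_cluster_count <- function(M, mult = 3) {
  stopifnot(M >= 1L, mult >= 1)
  lo <- as.integer(M)
  hi <- as.integer(floor(mult * M))
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

#' k-means clustering over a feature subspace
#'
#' Lloyd's algorithm on the rows of a data matrix with the Euclidean metric
#' restricted to a feature subset. Returned clusters carry full-dimension
#' centroids (over all L features, not just the subset) plus exact per-class
#' membership counts, which is what the support-matrix construction needs.
#'
#' Details, all deterministic given the RNG state on entry:
#' * initial centroids are `P` distinct instances sampled uniformly;
#' * assignment ties go to the lowest cluster index;
#' * a cluster left empty during an iteration keeps its previous centroid;
#' * iteration stops when assignments are unchanged or after `max_iter`;
#' * clusters empty at convergence are dropped from the result.
#'
#' Centroid coordinates are per-feature means; with `centroid_mode = "mode"`
#' (intended for binary data) each coordinate is the per-feature mode, with
#' the half-half tie resolved to 0. Mode centroids are used both during
#' iteration and in the returned clusters, so for binary data every returned
#' centroid coordinate is 0 or 1.
#'
#' @param dm A `"cbce_matrix"`.
#' @param subset A [sample_feature_subset()] result, or an integer vector of
#'   1-based feature positions; default all features.
#' @param P Number of clusters to seed (1 <= P <= N).
#' @param centroid_mode `"mean"` or `"mode"`.
#' @param max_iter Iteration cap (default 100).
#' @return A `"cluster_collection"`: list with `clusters` (each holding
#'   `centroid`, `n`, `class_counts` named by class), `subset`, `iterations`,
#'   `dropped` (empty clusters discarded at convergence), `centroid_mode`.
#' @export
subspace_kmeans <- function(dm, subset = NULL, P,
                            centroid_mode = c("mean", "mode"),
                            max_iter = 100L) {
  stopifnot(inherits(dm, "cbce_matrix"))
  centroid_mode <- match.arg(centroid_mode)
  x <- dm$x
  storage.mode(x) <- "double"
  N <- nrow(x)
  L <- ncol(x)
  if (is.null(subset)) subset <- seq_len(L)
  idx <- if (inherits(subset, "feature_subset")) subset$idx else
    sort(unique(as.integer(subset)))
  if (length(idx) < 1L || any(idx < 1L) || any(idx > L)) {
    stop("feature subset out of range", call. = FALSE)
  }
  P <- as.integer(P)
  if (P < 1L) stop("P must be at least 1", call. = FALSE)
  if (P > N) {
    stop("cannot seed ", P, " clusters from ", N, " instances", call. = FALSE)
  }

  centers <- x[sample.int(N, P), , drop = FALSE]
  assign_prev <- rep(0L, N)
  iterations <- 0L
  repeat {
    d2 <- cross_dist2(x, centers, idx)
    assignment <- max.col(-d2, ties.method = "first")
    iterations <- iterations + 1L
    if (identical(assignment, assign_prev) || iterations >= max_iter) break
    assign_prev <- assignment
    for (p in seq_len(P)) {
      members <- x[assignment == p, , drop = FALSE]
      if (nrow(members) > 0L) {
        centers[p, ] <- centroid_of(members, centroid_mode)
      }
    }
  }

  keep <- sort(unique(assignment))
  clusters <- lapply(keep, function(p) {
    members <- x[assignment == p, , drop = FALSE]
    counts <- table(factor(dm$labels[assignment == p], levels = dm$classes))
    list(centroid = centroid_of(members, centroid_mode),
         n = nrow(members),
         class_counts = stats::setNames(as.integer(counts), dm$classes))
  })
  structure(
    list(clusters = clusters, subset = idx,
         subset_raw = if (inherits(subset, "feature_subset")) subset$raw,
         iterations = iterations, dropped = P - length(keep),
         centroid_mode = centroid_mode),
    class = "cluster_collection"
  )
}

centroid_of <- function(members, centroid_mode) {
  m <- colMeans(members)
  if (centroid_mode == "mode") {
    # per-feature mode of 0/1 values; exact half-half tie resolved to 0
    m <- as.numeric(m > 0.5)
  }
  unname(m)
}

#' @export
print.cluster_collection <- function(x, ...) {
  cat("Cluster collection: ", length(x$clusters), " clusters over ",
      length(x$subset), " features (", x$iterations, " iterations, ",
      x$dropped, " empty dropped)\n", sep = "")
  invisible(x)
}
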