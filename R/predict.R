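#' Nearest cluster of a base classifier
#'
#' Finds the cluster whose centroid is closest to a query vector in the
#' *full* feature space (the per-classifier subset matters only while the
#' collection is built). Ties go to the lowest cluster index.
#'
#' @param x Numeric query vector of length L.
#' @param classifier A `"base_classifier"`.
#' @return List with `cluster` (1-based index into the retained clusters)
#'   and `distance` (root Euclidean).
#' @export
nearest_cluster <- function(x, classifier) {
  clusters <- classifier$clusters
  if (length(clusters) == 0L) {
    stop("base classifier has no retained clusters", call. = FALSE)
  }
  d <- vapply(clusters,
              function(cl) squared_distance(x, cl$centroid), numeric(1))
  i <- which.min(d)  # which.min takes the first minimum: lowest index wins
  list(cluster = i, distance = sqrt(d[i]))
}

#' Fused per-class support for a query instance
#'
#' Each base classifier contributes through its nearest cluster: with
#' support row `A` and centroid distance `d`, class `j` receives
#' `exp(A[j] / (1 + d))` unless `A[j] = -1` (no instance of the class in
#' the cluster), which contributes exactly 0. Shrinking the distance
#' amplifies whatever the cluster has to say: positive support grows,
#' negative support shrinks further.
#'
#' @param x Numeric query vector of length L (or an encoded feature vector).
#' @param ensemble A `"cbce"` model.
#' @return A `"support_vector"`: list with `support` (named non-negative
#'   per-class totals) and `trace` (data frame with one row per base
#'   classifier: selected cluster, distance, and its contribution per
#'   class in a matrix column `contrib`).
#' @export
class_support <- function(x, ensemble) {
  stopifnot(inherits(ensemble, "cbce"))
  x <- as.numeric(x)
  if (length(x) != length(ensemble$inventory)) {
    stop("query has ", length(x), " features; the model expects ",
         length(ensemble$inventory), call. = FALSE)
  }
  classes <- ensemble$classes
  total <- stats::setNames(numeric(length(classes)), classes)
  sel <- vapply(ensemble$classifiers, function(bc) {
    nc <- nearest_cluster(x, bc)
    c(nc$cluster, nc$distance)
  }, numeric(2))
  contrib <- vapply(seq_along(ensemble$classifiers), function(k) {
    bc <- ensemble$classifiers[[k]]
    a <- bc$support[sel[1L, k], ]
    ifelse(a > -1, exp(a / (1 + sel[2L, k])), 0)
  }, numeric(length(classes)))
  contrib <- matrix(contrib, ncol = length(classes), byrow = TRUE,
                    dimnames = list(NULL, classes))
  structure(
    list(support = colSums(contrib),
         trace = data.frame(classifier = seq_along(ensemble$classifiers),
                            cluster = as.integer(sel[1L, ]),
                            distance = sel[2L, ],
                            contrib = I(contrib))),
    class = "support_vector"
  )
}

#' @export
print.support_vector <- function(x, digits = 2L, ...) {
  cat("Fused class support\n")
  s <- round_half_up(x$support, digits)
  for (j in seq_along(s)) {
    cat(sprintf("  %-20s %s\n", names(s)[j], format(s[j])))
  }
  invisible(x)
}

#' Predict activity classes with a trained ensemble
#'
#' Computes [class_support()] for each query row and returns the class with
#' the highest fused support. Ties resolve to the class listed earlier in
#' the model's class order; a query for which every class receives zero
#' support falls back to the training-set majority class.
#'
#' @param object A `"cbce"` model.
#' @param newdata A `"cbce_matrix"`, a numeric matrix with one query per
#'   row, or a single feature vector.
#' @param type `"class"` (default) for labels, `"support"` for the N x M
#'   matrix of fused supports.
#' @param ... Ignored.
#' @return Character vector of class labels, or a support matrix.
#' @export
predict.cbce <- function(object, newdata, type = c("class", "support"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "cbce_matrix")) newdata$x else newdata
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1L)
  supports <- vapply(seq_len(nrow(x)),
                     function(i) class_support(x[i, ], object)$support,
                     numeric(length(object$classes)))
  supports <- matrix(supports, ncol = length(object$classes), byrow = TRUE,
                     dimnames = list(NULL, object$classes))
  if (type == "support") return(supports)
  apply(supports, 1L, function(s) {
    if (all(s == 0)) return(object$majority_class)
    object$classes[which.max(s)]  # first maximum: earlier class wins ties
  })
}
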