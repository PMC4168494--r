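#' Euclidean distance between two feature vectors
#'
#' Root Euclidean distance, optionally restricted to a feature subset (the
#' metric the cluster collections are built with; classification always uses
#' the full feature space).
#'
#' @param a,b Numeric vectors of equal length.
#' @param subset Optional integer vector of 1-based feature positions to
#'   restrict the metric to; default uses all positions.
#' @return Non-negative scalar.
#' @examples
#' euclidean_distance(c(0, 1, 0), c(0, 0, 0))
#' @export
euclidean_distance <- function(a, b, subset = NULL) {
  sqrt(squared_distance(a, b, subset))
}

#' Squared Euclidean distance
#'
#' Companion to [euclidean_distance()]; occasionally convenient when only
#' distance ranks matter, e.g. when illustrating why count encodings of the
#' same activity can land far apart.
#'
#' @inheritParams euclidean_distance
#' @return Non-negative scalar.
#' @export
squared_distance <- function(a, b, subset = NULL) {
  if (length(a) != length(b)) {
    stop("vectors differ in length (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  }
  d <- as.numeric(a) - as.numeric(b)
  if (!is.null(subset)) d <- d[subset]
  sum(d * d)
}

# Squared Euclidean distances from every row of x to every row of centers,
# over the given feature subset. Returns an nrow(x) x nrow(centers) matrix.
# Clamps tiny negative values from the expansion identity.
cross_dist2 <- function(x, centers, subset = NULL) {
  if (!is.null(subset)) {
    x <- x[, subset, drop = FALSE]
    centers <- centers[, subset, drop = FALSE]
  }
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) -
    2 * x %*% t(centers)
  d2[d2 < 0] <- 0
  d2
}
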