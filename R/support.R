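#' Support matrix of a cluster collection
#'
#' Scores how strongly each cluster backs each activity class. With `N_i`
#' instances in cluster `i`, `N_ij` of them from class `j`, and `M` classes,
#' the benchmark `N_i / M` is the membership a class would get if the
#' cluster mixed all classes evenly, and the support is
#'
#' \deqn{A[i,j] = \frac{N_{ij} - N_i/M}{N_i - N_i/M} \quad
#'       \textrm{if } N_{ij} \ge N_i/M, \qquad
#'       A[i,j] = \frac{N_{ij} - N_i/M}{N_i/M} \quad \textrm{otherwise.}}
#'
#' Each entry lies in `[-1, 1]`: 1 for a cluster pure in the class, -1 when
#' the class is absent, 0 at exactly-even mixing. With a single class the
#' above-average branch is degenerate (`N_i - N_i/M = 0`) and the support is
#' defined as 1 — every cluster is pure by construction.
#'
#' Values are kept at full precision; round only for display.
#'
#' @param counts Matrix of per-class membership counts, one row per cluster
#'   and one column per class, or a `"cluster_collection"` from
#'   [subspace_kmeans()] (counts are then taken from its clusters).
#' @param M Number of classes; defaults to `ncol(counts)`.
#' @return Numeric matrix of supports, same shape as `counts`, preserving
#'   dimnames.
#' @examples
#' compute_support_matrix(rbind(c(14, 0, 0, 17, 0, 2, 0)))
#' @export
compute_support_matrix <- function(counts, M = NULL) {
  if (inherits(counts, "cluster_collection")) {
    counts <- do.call(rbind, lapply(counts$clusters, `[[`, "class_counts"))
  }
  counts <- as.matrix(counts)
  if (is.null(M)) M <- ncol(counts)
  if (M < 1L) stop("at least one class is required", call. = FALSE)
  if (ncol(counts) != M) {
    stop("counts have ", ncol(counts), " columns but M = ", M, call. = FALSE)
  }
  if (nrow(counts) > 0 && (anyNA(counts) || any(counts < 0))) {
    stop("membership counts must be non-negative", call. = FALSE)
  }
  n_i <- rowSums(counts)
  if (any(n_i == 0)) {
    stop("empty cluster(s) have no defined support row", call. = FALSE)
  }
  if (M == 1L) {
    a <- matrix(1, nrow(counts), 1L)
    dimnames(a) <- dimnames(counts)
    return(a)
  }
  avg <- n_i / M
  dev <- sweep(counts, 1L, avg)
  denom_hi <- n_i - avg
  a <- ifelse(dev >= 0, dev / denom_hi, sweep(dev, 1L, avg, "/"))
  dimnames(a) <- dimnames(counts)
  a
}

#' Round half away from zero
#'
#' Display rounding used in all user-facing support and fusion reports
#' (base `round()` rounds half to even, which does not match the usual
#' hand-computed tables).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return `x` rounded with halves going away from zero.
#' @export
round_half_up <- function(x, digits = 0L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}
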