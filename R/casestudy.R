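# Bundled worked example: a compact three-classifier ensemble over the
# default 14-sensor / 7-activity layout, with binary (mode) centroids,
# per-cluster class membership counts, and the support matrices as they are
# conventionally displayed (rounded to the precision shown in reports).
# Used by the documentation, the CLI demo and the regression tests; no
# training is needed to exercise the full classification path.

casestudy_classes <- function() {
  c("go-to-bed", "use-toilet", "prepare-breakfast", "take-shower",
    "get-drink", "prepare-dinner", "leave-house")
}

casestudy_data <- function() {
  cents1 <- matrix(c(
    0,1,0,0,0,0,0,0,0,0,0,0,0,0,
    0,0,0,0,0,0,1,0,0,0,0,0,0,0,
    0,0,1,0,0,0,0,0,1,0,0,0,0,0,
    0,0,0,1,1,0,0,0,0,0,0,0,0,0,
    0,0,0,0,1,1,0,0,0,0,0,0,1,0,
    0,0,0,1,0,0,0,0,0,0,0,0,0,0,
    0,0,0,0,0,0,0,0,1,0,0,0,0,0,
    0,0,1,0,0,0,0,0,0,0,0,0,0,0,
    1,0,0,1,1,1,0,0,0,1,1,0,1,0,
    0,0,0,1,0,1,0,1,0,0,1,0,1,0,
    0,0,0,1,1,0,0,1,0,1,0,0,0,0,
    0,0,0,0,1,1,0,0,0,1,1,0,1,0,
    0,0,0,0,1,1,0,1,0,1,1,0,0,0), ncol = 14, byrow = TRUE)
  counts1 <- matrix(c(
    14,0,0,17,0,2,0,
    0,0,0,0,0,0,25,
    0,69,0,0,0,0,0,
    0,0,1,0,12,0,0,
    0,0,16,0,2,0,0,
    0,0,0,0,1,0,0,
    0,13,0,0,0,0,0,
    0,10,0,1,0,0,0,
    0,0,1,0,0,3,0,
    0,0,0,0,0,1,0,
    0,0,0,0,1,0,0,
    0,0,0,0,0,2,0,
    0,0,1,0,0,0,0), ncol = 7, byrow = TRUE)
  supp1 <- matrix(c(
    0.3,-1,-1,0.4,-1,-0.6,-1,
    -1,-1,-1,-1,-1,-1,1,
    -1,1,-1,-1,-1,-1,-1,
    -1,-1,-0.5,-1,0.9,-1,-1,
    -1,-1,0.9,-1,-0.2,-1,-1,
    -1,-1,-1,-1,1,-1,-1,
    -1,1,-1,-1,-1,-1,-1,
    -1,0.9,-1,-0.4,-1,-1,-1,
    -1,-1,0.1,-1,-1,0.7,-1,
    -1,-1,-1,-1,-1,1,-1,
    -1,-1,-1,-1,1,-1,-1,
    -1,-1,-1,-1,-1,1,-1,
    -1,-1,1,-1,-1,-1,-1), ncol = 7, byrow = TRUE)

  cents2 <- matrix(c(
    0,0,0,0,0,0,0,0,0,0,0,0,0,1,
    0,1,0,0,0,0,0,0,0,0,0,0,0,0,
    0,0,0,0,0,0,1,0,0,0,0,0,0,0,
    0,0,1,0,0,0,0,0,1,0,0,0,0,0,
    0,1,0,0,0,0,1,0,0,0,0,0,0,0,
    0,0,0,1,1,0,0,0,0,0,0,0,0,0,
    0,1,1,0,0,0,0,0,1,0,0,0,0,0,
    1,0,0,0,0,1,0,0,0,1,0,0,0,0,
    0,0,0,0,1,1,0,0,0,0,0,0,1,0,
    0,0,0,1,0,0,0,0,0,0,0,0,0,0,
    0,1,0,0,0,0,0,0,1,0,0,0,0,0), ncol = 14, byrow = TRUE)
  counts2 <- matrix(c(
    14,0,0,0,0,0,0,
    0,2,1,18,0,0,0,
    0,0,0,0,0,0,24,
    0,74,0,0,0,0,0,
    0,0,0,0,0,0,1,
    0,0,2,0,13,3,0,
    0,11,0,0,0,0,0,
    0,0,2,0,0,2,0,
    0,0,14,0,2,2,0,
    0,0,0,0,1,1,0,
    0,5,0,0,0,0,0), ncol = 7, byrow = TRUE)
  supp2 <- matrix(c(
    1,-1,-1,-1,-1,-1,-1,
    -1,-0.3,-0.7,0.8,-1,-1,-1,
    -1,-1,-1,-1,-1,-1,1,
    -1,1,-1,-1,-1,-1,-1,
    -1,-1,-1,-1,-1,-1,1,
    -1,-1,-0.2,-1,0.7,0.03,-1,
    -1,1,-1,-1,-1,-1,-1,
    -1,-1,0.4,-1,-1,0.4,-1,
    -1,-1,0.7,-1,-0.2,-0.2,-1,
    -1,-1,-1,-1,0.4,0.4,-1,
    -1,1,-1,-1,-1,-1,-1), ncol = 7, byrow = TRUE)

  cents3 <- matrix(c(
    0,0,0,0,0,0,0,0,0,0,0,0,0,1,
    0,1,0,0,0,0,0,0,0,0,0,0,0,0,
    0,0,1,0,0,0,0,0,1,0,0,0,0,0,
    0,0,0,1,1,0,0,0,0,0,0,0,0,0,
    0,0,0,0,0,1,0,0,0,1,0,0,1,0,
    0,0,0,0,1,1,0,0,0,0,0,0,1,0,
    0,1,0,0,0,0,0,0,0,0,0,0,0,1), ncol = 14, byrow = TRUE)
  counts3 <- matrix(c(
    9,3,0,0,0,0,0,
    0,18,0,18,0,0,1,
    0,71,0,0,1,0,24,
    0,0,1,0,15,0,0,
    0,0,0,0,0,3,0,
    0,0,18,0,0,5,0,
    5,0,0,0,0,0,0), ncol = 7, byrow = TRUE)
  supp3 <- matrix(c(
    0.7,0.1,-1,-1,-1,-1,-1,
    -1,0.4,-1,0.4,-1,-1,-0.8,
    -1,0.7,-1,-1,-0.9,-1,0.1,
    -1,-1,-0.6,-1,0.9,-1,-1,
    -1,-1,-1,-1,-1,1,-1,
    -1,-1,0.8,-1,-1,0.1,-1,
    1,-1,-1,-1,-1,-1,-1), ncol = 7, byrow = TRUE)

  list(
    list(centroids = cents1, counts = counts1, support = supp1),
    list(centroids = cents2, counts = counts2, support = supp2),
    list(centroids = cents3, counts = counts3, support = supp3)
  )
}

#' Bundled worked-example ensemble
#'
#' A ready-made three-classifier ensemble over the default 14-sensor /
#' 7-activity layout ([kasteren_inventory()]), small enough to follow by
#' hand: every centroid is a 0/1 vector and every cluster's per-class
#' membership counts are included. It exercises the complete classification
#' path (nearest cluster, support lookup, exponential fusion) with no
#' training step.
#'
#' @param support `"display"` (default) uses the support matrices at the
#'   precision they are conventionally displayed, so hand-checked fusion
#'   values are reproduced exactly; `"recomputed"` rebuilds every support
#'   row from the membership counts at full precision via
#'   [compute_support_matrix()].
#' @return A `"cbce"` model with `K = 3`.
#' @examples
#' fit <- casestudy_ensemble()
#' predict(fit, casestudy_instance())
#' @export
casestudy_ensemble <- function(support = c("display", "recomputed")) {
  support <- match.arg(support)
  classes <- casestudy_classes()
  colls <- casestudy_data()
  classifiers <- lapply(seq_along(colls), function(k) {
    coll <- colls[[k]]
    a <- if (support == "display") coll$support else
      compute_support_matrix(coll$counts)
    colnames(a) <- classes
    clusters <- lapply(seq_len(nrow(coll$centroids)), function(i) {
      list(centroid = coll$centroids[i, ],
           n = sum(coll$counts[i, ]),
           class_counts = stats::setNames(as.integer(coll$counts[i, ]),
                                          classes))
    })
    structure(
      list(k = k, subset = seq_len(14L), subset_raw = NULL,
           P = nrow(coll$centroids), clusters = clusters, support = a,
           dropped = 0L, iterations = NA_integer_, seed = NA_integer_),
      class = "base_classifier"
    )
  })
  structure(
    list(classifiers = classifiers, classes = classes, encoding = "binary",
         inventory = kasteren_inventory(), majority_class = "use-toilet",
         seed = NA_integer_, K = 3L, cluster_mult = 3,
         centroid_mode = "mode"),
    class = "cbce"
  )
}

#' Query instance for the bundled worked example
#'
#' A binary-encoded activity that activated the plates cupboard and the
#' freezer once each — a short dinner-preparation segment under the default
#' inventory.
#'
#' @return Binary feature vector of length 14 named by sensor.
#' @export
casestudy_instance <- function() {
  inv <- kasteren_inventory()
  encode_binary(c("Plates cupboard", "Freezer"), inv)
}
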