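#' Save a trained ensemble as JSON
#'
#' Writes a versioned, self-contained JSON document: class order, encoding,
#' inventory, majority class, seeds, and for every base classifier its
#' feature subset, cluster centroids, membership counts and support matrix.
#' Numbers are written at full precision so [load_cbce()] reconstructs a
#' model that predicts identically.
#'
#' @param ensemble A `"cbce"` model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_cbce <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "cbce"))
  doc <- list(
    format = "cbce-model", version = 1L,
    classes = ensemble$classes,
    encoding = ensemble$encoding,
    inventory = as.character(unclass(ensemble$inventory)),
    majority_class = ensemble$majority_class,
    seed = ensemble$seed, K = ensemble$K,
    cluster_mult = ensemble$cluster_mult,
    centroid_mode = ensemble$centroid_mode,
    classifiers = lapply(ensemble$classifiers, function(bc) {
      list(k = bc$k, seed = bc$seed, subset = as.integer(bc$subset),
           subset_raw = as.integer(bc$subset_raw), P = bc$P,
           dropped = bc$dropped, iterations = bc$iterations,
           clusters = lapply(bc$clusters, function(cl) {
             list(centroid = cl$centroid, n = cl$n,
                  class_counts = unname(cl$class_counts))
           }),
           support = unname(apply(bc$support, 1L, as.numeric,
                                  simplify = FALSE)))
    })
  )
  # I(17) significant digits: exact binary64 round trip
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Load an ensemble saved by [save_cbce()]
#'
#' @param path Path to the model JSON.
#' @return A `"cbce"` model.
#' @export
load_cbce <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(doc$format, "cbce-model")) {
    stop(path, " is not a cbce model file", call. = FALSE)
  }
  classes <- as.character(doc$classes)
  classifiers <- lapply(doc$classifiers, function(b) {
    support <- do.call(rbind, lapply(b$support, as.numeric))
    colnames(support) <- classes
    structure(
      list(k = as.integer(b$k), subset = as.integer(b$subset),
           subset_raw = as.integer(b$subset_raw), P = as.integer(b$P),
           clusters = lapply(b$clusters, function(cl) {
             list(centroid = as.numeric(cl$centroid), n = as.integer(cl$n),
                  class_counts = stats::setNames(as.integer(cl$class_counts),
                                                 classes))
           }),
           support = support, dropped = as.integer(b$dropped),
           iterations = as.integer(b$iterations),
           seed = if (!is.null(b$seed)) as.integer(b$seed)),
      class = "base_classifier"
    )
  })
  structure(
    list(classifiers = classifiers, classes = classes,
         encoding = doc$encoding,
         inventory = sensor_inventory(doc$inventory),
         majority_class = doc$majority_class,
         seed = if (!is.null(doc$seed)) as.integer(doc$seed),
         K = as.integer(doc$K), cluster_mult = doc$cluster_mult,
         centroid_mode = doc$centroid_mode),
    class = "cbce"
  )
}
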