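#' Encode an activity instance as per-sensor occurrence counts
#'
#' The numeric representation of a segmented activity: position `p` of the
#' result holds how many times sensor `p` of the inventory fired during the
#' segment. The encoding is order-free — permuting the event sequence leaves
#' it unchanged — so any signal carried by event order is deliberately lost.
#'
#' @param instance An [activity_instance()], or a plain character vector of
#'   sensor labels.
#' @param inventory A [sensor_inventory()] fixing vector positions.
#' @param on_unknown What to do with a sensor label absent from the
#'   inventory: `"error"` (default; treats it as malformed input) or
#'   `"ignore"` (drop the event).
#' @return Integer vector of length `length(inventory)` named by sensor
#'   label, with attributes `encoding = "numeric"` and `activity`.
#' @examples
#' inv <- kasteren_inventory()
#' seq <- c("Hall-Bathroom door", rep("Toilet Flush", 3), "Hall-Bathroom door")
#' encode_numeric(seq, inv)
#' @export
encode_numeric <- function(instance, inventory,
                           on_unknown = c("error", "ignore")) {
  on_unknown <- match.arg(on_unknown)
  sensors <- resolve_sensors(instance, inventory, on_unknown)
  v <- tabulate(match(sensors, unclass(inventory)), nbins = length(inventory))
  feature_vector(v, inventory, "numeric", instance_activity(instance))
}

#' Encode an activity instance as per-sensor presence indicators
#'
#' The binary representation: position `p` is 1 if sensor `p` fired at least
#' once during the segment and 0 otherwise. Equivalent to thresholding
#' [encode_numeric()] at one occurrence.
#'
#' @inheritParams encode_numeric
#' @return Integer 0/1 vector of length `length(inventory)` with attributes
#'   `encoding = "binary"` and `activity`.
#' @examples
#' inv <- kasteren_inventory()
#' seq <- c("Hall-Bathroom door", rep("Toilet Flush", 3), "Hall-Bathroom door")
#' encode_binary(seq, inv)
#' @export
encode_binary <- function(instance, inventory,
                          on_unknown = c("error", "ignore")) {
  v <- encode_numeric(instance, inventory, on_unknown)
  out <- as.integer(v >= 1L)
  feature_vector(out, inventory, "binary", attr(v, "activity"))
}

feature_vector <- function(values, inventory, encoding, activity = NA) {
  structure(as.integer(values), names = unclass(inventory),
            encoding = encoding, activity = activity)
}

instance_activity <- function(instance) {
  if (inherits(instance, "activity_instance")) instance$activity else NA_character_
}

resolve_sensors <- function(instance, inventory, on_unknown) {
  if (!inherits(inventory, "sensor_inventory")) {
    inventory <- sensor_inventory(inventory)
  }
  sensors <- if (inherits(instance, "activity_instance")) {
    instance$sensors
  } else {
    as.character(instance)
  }
  unknown <- setdiff(sensors, unclass(inventory))
  if (length(unknown)) {
    if (on_unknown == "error") {
      stop("unknown sensor label(s): ", paste(unique(unknown), collapse = ", "),
           call. = FALSE)
    }
    sensors <- sensors[sensors %in% unclass(inventory)]
  }
  sensors
}

#' Assemble a data matrix from activity instances
#'
#' Encodes a list of segmented instances against one shared inventory and
#' stacks them into the tabular container the trainer and evaluator consume:
#' an N x L matrix of feature values, class labels, and an ordered class
#' list.
#'
#' @param instances List of [activity_instance()] objects.
#' @param inventory A [sensor_inventory()].
#' @param encoding `"binary"` or `"numeric"`.
#' @param classes Optional ordered character vector of class labels; defaults
#'   to the sorted unique instance labels. Must cover every label present.
#' @param on_unknown Passed to the encoders.
#' @return A `"cbce_matrix"`: list with components `x` (integer matrix, one
#'   row per instance, sensor labels as column names), `labels` (character,
#'   length N), `classes` (ordered, length M), `encoding`, `inventory`.
#' @export
encode_instances <- function(instances, inventory,
                             encoding = c("binary", "numeric"),
                             classes = NULL,
                             on_unknown = c("error", "ignore")) {
  encoding <- match.arg(encoding)
  on_unknown <- match.arg(on_unknown)
  encoder <- if (encoding == "binary") encode_binary else encode_numeric
  rows <- lapply(instances, encoder, inventory = inventory,
                 on_unknown = on_unknown)
  x <- do.call(rbind, lapply(rows, as.integer))
  if (is.null(x)) x <- matrix(integer(), 0L, length(inventory))
  colnames(x) <- unclass(inventory)
  labels <- vapply(instances, instance_activity, character(1))
  cbce_matrix(x, labels, encoding, inventory, classes)
}

#' Construct a data matrix directly from encoded rows
#'
#' Low-level constructor for pre-encoded instance tables (e.g. read from
#' CSV). Validates dimensions, encoding-specific value constraints and class
#' coverage.
#'
#' @param x Numeric matrix, one instance per row, `L` columns.
#' @param labels Class label per row (`NA` allowed for unlabelled rows).
#' @param encoding `"binary"` (all values 0/1) or `"numeric"` (non-negative
#'   integer counts).
#' @param inventory A [sensor_inventory()] with `L` labels; defaults to the
#'   matrix column names.
#' @param classes Optional ordered class list covering all row labels.
#' @return A `"cbce_matrix"` (see [encode_instances()]).
#' @export
cbce_matrix <- function(x, labels, encoding = c("binary", "numeric"),
                        inventory = NULL, classes = NULL) {
  encoding <- match.arg(encoding)
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (is.null(inventory)) {
    if (is.null(colnames(x))) {
      stop("supply an inventory or a matrix with sensor column names",
           call. = FALSE)
    }
    inventory <- sensor_inventory(colnames(x))
  }
  if (!inherits(inventory, "sensor_inventory")) {
    inventory <- sensor_inventory(inventory)
  }
  if (ncol(x) != length(inventory)) {
    stop("matrix has ", ncol(x), " columns but the inventory lists ",
         length(inventory), " sensors", call. = FALSE)
  }
  colnames(x) <- unclass(inventory)
  if (nrow(x) > 0 && (anyNA(x) || any(x < 0L))) {
    stop("feature values must be non-negative and non-missing", call. = FALSE)
  }
  if (encoding == "binary" && nrow(x) > 0 && any(x > 1L)) {
    stop("binary-encoded values must all be 0 or 1", call. = FALSE)
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) {
    stop("need one class label per row", call. = FALSE)
  }
  seen <- unique(labels[!is.na(labels)])
  if (is.null(classes)) {
    classes <- sort(seen)
  } else {
    classes <- as.character(classes)
    if (anyDuplicated(classes)) stop("duplicate class labels", call. = FALSE)
    missing <- setdiff(seen, classes)
    if (length(missing)) {
      stop("row label(s) outside the class list: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  if (length(classes) < 1L && any(!is.na(labels))) {
    stop("at least one class label is required", call. = FALSE)
  }
  # a table with no labels at all (all NA, no class list) is a query-only
  # table: usable for prediction, rejected by the trainer
  structure(
    list(x = x, labels = labels, classes = classes, encoding = encoding,
         inventory = inventory),
    class = "cbce_matrix"
  )
}

#' @export
print.cbce_matrix <- function(x, ...) {
  cat("cbce data matrix: ", nrow(x$x), " instances x ", ncol(x$x),
      " sensors (", x$encoding, " encoding), ",
      length(x$classes), " classes\n", sep = "")
  invisible(x)
}

#' @export
dim.cbce_matrix <- function(x) dim(x$x)

#' Subset the rows of a data matrix
#'
#' @param x A `"cbce_matrix"`.
#' @param i Row index vector.
#' @param ... Ignored.
#' @return A `"cbce_matrix"` with the selected rows and unchanged class list.
#' @export
`[.cbce_matrix` <- function(x, i, ...) {
  cbce_matrix(x$x[i, , drop = FALSE], x$labels[i], x$encoding,
              x$inventory, x$classes)
}
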