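#' Read annotated sensor events from CSV
#'
#' Expects one row per sensor event with columns `segment_id`, `sensor`,
#' `activity` and optionally `timestamp` (ISO-8601, preserved verbatim).
#' Rows must appear in occurrence order within each segment; every row of a
#' segment must carry the same activity label.
#'
#' @param path Path to the event CSV.
#' @param inventory Optional [sensor_inventory()]; when supplied, sensor
#'   labels are validated against it up front and the offending row is named
#'   in the error.
#' @return List of [activity_instance()] objects, one per segment, in order
#'   of first appearance.
#' @export
read_events <- function(path, inventory = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("segment_id", "sensor", "activity")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("event file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.null(inventory)) {
    bad <- which(!(df$sensor %in% unclass(inventory)))
    if (length(bad)) {
      stop("unknown sensor label '", df$sensor[bad[1L]], "' at data row ",
           bad[1L], " of ", path, call. = FALSE)
    }
  }
  ids <- unique(df$segment_id)
  lapply(ids, function(id) {
    seg <- df[df$segment_id == id, , drop = FALSE]
    acts <- unique(seg$activity)
    if (length(acts) > 1L) {
      stop("segment ", id, " carries conflicting activity labels: ",
           paste(acts, collapse = ", "), call. = FALSE)
    }
    activity_instance(
      sensors = seg$sensor, activity = acts,
      segment_id = id,
      timestamps = if ("timestamp" %in% names(seg)) seg$timestamp
    )
  })
}

#' Write annotated sensor events to CSV
#'
#' Inverse of [read_events()]: one row per event, occurrence order preserved
#' within each segment.
#'
#' @param instances List of [activity_instance()] objects with unique
#'   segment ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(instances, path) {
  ids <- vapply(instances, function(z) as.character(z$segment_id), character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate segment id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  rows <- lapply(instances, function(z) {
    n <- length(z$sensors)
    if (n == 0L) return(NULL)
    out <- data.frame(segment_id = rep(as.character(z$segment_id), n),
                      sensor = z$sensors,
                      activity = rep(z$activity, n),
                      stringsAsFactors = FALSE)
    if (!is.null(z$timestamps)) out$timestamp <- as.character(z$timestamps)
    out
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(segment_id = character(), sensor = character(),
                     activity = character())
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an encoded instance table
#'
#' CSV layout: one header row of sensor labels plus a final `class` column,
#' one instance per row. JSON layout: an object with fields `inventory`,
#' `encoding`, `classes`, `rows` (values) and `labels`, as written by
#' [write_matrix()].
#'
#' @param path Input path.
#' @param encoding For CSV input, the encoding the values are in (inferred
#'   as `"binary"` when all values are 0/1 unless stated). Ignored for JSON,
#'   which records it.
#' @param format `"csv"` or `"json"`; default guesses from the extension.
#' @return A `"cbce_matrix"`.
#' @export
read_matrix <- function(path, encoding = NULL,
                        format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    need <- c("inventory", "encoding", "rows", "labels")
    missing <- setdiff(need, names(doc))
    if (length(missing)) {
      stop("matrix file ", path, " is missing field(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    x <- if (is.matrix(doc$rows)) doc$rows else
      do.call(rbind, lapply(doc$rows, as.integer))
    labels <- doc$labels
    if (length(labels) == 0L) labels <- rep(NA_character_, nrow(x))
    return(cbce_matrix(x, labels, doc$encoding,
                       sensor_inventory(doc$inventory), doc$classes))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"class" %in% names(df)) {
    stop("matrix file ", path, " has no 'class' column", call. = FALSE)
  }
  labels <- as.character(df$class)
  x <- as.matrix(df[setdiff(names(df), "class")])
  if (is.null(encoding)) {
    encoding <- if (nrow(x) == 0L || all(x %in% c(0L, 1L))) "binary" else "numeric"
  }
  cbce_matrix(x, labels, encoding)
}

#' Write an encoded instance table
#'
#' @param dm A `"cbce_matrix"`.
#' @param path Output path.
#' @param format `"csv"` (sensor columns + `class`) or `"json"` (records the
#'   inventory, encoding and class order explicitly, so the round trip is
#'   exact). Default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(dm, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(dm, "cbce_matrix"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    doc <- list(inventory = as.character(unclass(dm$inventory)),
                encoding = dm$encoding,
                classes = dm$classes,
                labels = dm$labels,
                rows = unname(apply(dm$x, 1L, as.integer, simplify = FALSE)))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    df <- as.data.frame(dm$x, check.names = FALSE)
    df$class <- dm$labels
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
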