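#' Sensor inventory
#'
#' An ordered roster of sensor labels defining the layout of all feature
#' vectors: position `p` of every encoded vector corresponds to the `p`-th
#' label of the inventory. Positions are fixed by the order in which labels
#' are supplied, not by any numeric id embedded in the label.
#'
#' @param labels Character vector of unique sensor labels, in vector-position
#'   order. At least one label is required.
#' @return An object of class `"sensor_inventory"`: the label vector with the
#'   position map implied by its order.
#' @examples
#' inv <- sensor_inventory(c("Fridge", "Front door", "Toilet Flush"))
#' length(inv)
#' @seealso [kasteren_inventory()] for the bundled 14-sensor default layout.
#' @export
sensor_inventory <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 1L) {
    stop("a sensor inventory needs at least one label", call. = FALSE)
  }
  if (anyNA(labels) || any(!nzchar(labels))) {
    stop("sensor labels must be non-empty and non-missing", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    dup <- unique(labels[duplicated(labels)])
    stop("duplicate sensor label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  structure(labels, class = "sensor_inventory")
}

#' Default 14-sensor smart-home inventory
#'
#' The wireless object sensors of the single-resident apartment deployment
#' that the package's worked examples use (microwave, doors, cupboards,
#' fridge, freezer, toilet flush, ...), in the fixed vector-position order
#' all bundled fixtures assume.
#'
#' @return A [sensor_inventory()] of 14 labels.
#' @export
kasteren_inventory <- function() {
  sensor_inventory(c(
    "Microwave", "Hall-Toilet door", "Hall-Bathroom door", "Cups cupboard",
    "Fridge", "Plates cupboard", "Front door", "Dishwasher", "Toilet Flush",
    "Freezer", "Pans Cupboard", "Washing machine", "Groceries Cupboard",
    "Hall-Bedroom door"
  ))
}

#' @export
print.sensor_inventory <- function(x, ...) {
  cat("Sensor inventory (", length(x), " sensors)\n", sep = "")
  cat(paste0("  [", seq_along(x), "] ", unclass(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Segmented activity instance
#'
#' One pre-segmented activity: the ordered sequence of sensor labels fired
#' while the activity was performed, plus an optional ground-truth activity
#' label. Timestamps, when present, are carried along unmodified; the
#' classifier itself never uses them.
#'
#' @param sensors Character vector of sensor labels in occurrence order
#'   (may be empty).
#' @param activity Activity class label, or `NA` for unlabelled queries.
#' @param segment_id Identifier of the activity segment.
#' @param timestamps Optional vector, same length as `sensors`.
#' @return An object of class `"activity_instance"`.
#' @export
activity_instance <- function(sensors = character(), activity = NA_character_,
                              segment_id = NA, timestamps = NULL) {
  sensors <- as.character(sensors)
  if (!is.null(timestamps) && length(timestamps) != length(sensors)) {
    stop("timestamps must match the sensor sequence in length", call. = FALSE)
  }
  structure(
    list(segment_id = segment_id, sensors = sensors,
         activity = as.character(activity)[1L], timestamps = timestamps),
    class = "activity_instance"
  )
}

#' @export
print.activity_instance <- function(x, ...) {
  cat("Activity instance", if (!is.na(x$segment_id)) paste0("#", x$segment_id),
      "\n  events: ", length(x$sensors),
      "\n  activity: ", if (is.na(x$activity)) "<unlabelled>" else x$activity,
      "\n", sep = "")
  invisible(x)
}
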