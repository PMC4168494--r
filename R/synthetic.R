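#' Activity template for the synthetic event simulator
#'
#' One activity class is described by a per-sensor activation probability
#' (which sensors tend to fire during the activity), a per-template
#' occurrence-count mean (how often an activated sensor fires, geometric
#' with mean `count_mean`), and a frequency weight (how often the activity
#' occurs relative to the others).
#'
#' @param label Activity class label.
#' @param probs Named numeric vector of activation probabilities in `[0,1]`,
#'   names drawn from the sensor inventory; sensors omitted never fire
#'   (except through noise). At least one probability must be positive.
#' @param count_mean Mean occurrence count of an activated sensor (>= 1).
#' @param weight Relative frequency weight (> 0).
#' @return An `"activity_template"`.
#' @export
activity_template <- function(label, probs, count_mean = 1.5, weight = 1) {
  probs <- unlist(probs)
  if (is.null(names(probs)) || any(!nzchar(names(probs)))) {
    stop("activation probabilities must be named by sensor", call. = FALSE)
  }
  if (any(probs < 0) || any(probs > 1)) {
    stop("activation probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!any(probs > 0)) {
    stop("template '", label, "' activates no sensor", call. = FALSE)
  }
  stopifnot(count_mean >= 1, weight > 0)
  structure(list(label = as.character(label), probs = probs,
                 count_mean = count_mean, weight = weight),
            class = "activity_template")
}

#' Synthetic smart-home dataset configuration
#'
#' Bundles the activity templates with the dataset-level knobs: the number
#' of instances to draw, a noise rate (the probability that each sensor
#' outside the template fires once spuriously in a segment), and the sensor
#' inventory the templates refer to.
#'
#' @param templates List of [activity_template()] objects with distinct
#'   labels.
#' @param n Number of instances to generate (>= 1).
#' @param inventory A [sensor_inventory()]; defaults to the union of the
#'   template sensors in first-appearance order.
#' @param noise Spurious-activation probability per non-template sensor,
#'   in `[0, 1]` (default 0).
#' @return A `"synthetic_config"`.
#' @export
synthetic_config <- function(templates, n, inventory = NULL, noise = 0) {
  stopifnot(length(templates) >= 1L)
  labels <- vapply(templates, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("duplicate template labels", call. = FALSE)
  }
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be at least 1", call. = FALSE)
  if (noise < 0 || noise > 1) stop("noise must lie in [0, 1]", call. = FALSE)
  sensors <- unique(unlist(lapply(templates, function(t) names(t$probs))))
  if (is.null(inventory)) {
    inventory <- sensor_inventory(sensors)
  } else {
    if (!inherits(inventory, "sensor_inventory")) {
      inventory <- sensor_inventory(inventory)
    }
    missing <- setdiff(sensors, unclass(inventory))
    if (length(missing)) {
      stop("template sensor(s) absent from the inventory: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(templates = templates, n = n, inventory = inventory,
                 noise = noise),
            class = "synthetic_config")
}

#' Generate synthetic annotated activity instances
#'
#' For each instance a template is drawn by frequency weight, each template
#' sensor is activated with its probability, each activated sensor fires a
#' geometric number of times (mean `count_mean`), noise sensors fire once
#' with probability `noise`, and the resulting event multiset is emitted in
#' random order — the encodings downstream are order-free, so order carries
#' no signal by construction. A draw that activates no sensor at all falls
#' back to the template's highest-probability sensor, so every instance has
#' at least one event.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed (required; generation is fully deterministic
#'   given it).
#' @return List of [activity_instance()] objects with ground-truth labels.
#' @export
generate_instances <- function(config, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (missing(seed) || is.null(seed)) {
    stop("an integer seed is required", call. = FALSE)
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  weights <- vapply(config$templates, `[[`, numeric(1), "weight")
  weights <- weights / sum(weights)
  all_sensors <- unclass(config$inventory)
  picks <- sample.int(length(config$templates), config$n, replace = TRUE,
                      prob = weights)
  lapply(seq_len(config$n), function(i) {
    tpl <- config$templates[[picks[i]]]
    on_sensors <- names(tpl$probs)[stats::runif(length(tpl$probs)) < tpl$probs]
    if (length(on_sensors) == 0L) {
      on_sensors <- names(tpl$probs)[which.max(tpl$probs)]
    }
    counts <- 1L + stats::rgeom(length(on_sensors),
                                prob = 1 / tpl$count_mean)
    events <- rep(on_sensors, counts)
    if (config$noise > 0) {
      off <- setdiff(all_sensors, names(tpl$probs)[tpl$probs > 0])
      spurious <- off[stats::runif(length(off)) < config$noise]
      events <- c(events, spurious)
    }
    events <- events[sample.int(length(events))]
    activity_instance(sensors = events, activity = tpl$label, segment_id = i)
  })
}

#' Templates with block signatures and a controllable overlap
#'
#' Builds one template per class from disjoint blocks of
#' `sensors_per_class` sensors, then makes consecutive class pairs
#' (1-2, 3-4, ...) confusable by sharing a fraction `overlap` of their
#' block sensors. With `overlap = 0` every class has a disjoint sensor
#' signature and is perfectly recoverable; with `overlap = 1` paired
#' classes use identical sensor sets and are statistically exchangeable.
#'
#' @param n_classes Number of activity classes.
#' @param sensors_per_class Signature size per class (default 2).
#' @param overlap Fraction in `[0, 1]` of each paired class's signature
#'   replaced by the partner's sensors.
#' @param activation Activation probability of signature sensors
#'   (default 0.9).
#' @param count_mean Occurrence-count mean, recycled over classes.
#' @return List of [activity_template()] objects (labels `"act1"`, ...).
#' @export
signature_templates <- function(n_classes, sensors_per_class = 2L,
                                overlap = 0, activation = 0.9,
                                count_mean = 1.5) {
  stopifnot(n_classes >= 1L, sensors_per_class >= 1L,
            overlap >= 0, overlap <= 1)
  count_mean <- rep_len(count_mean, n_classes)
  blocks <- lapply(seq_len(n_classes), function(c) {
    paste0("sensor", (c - 1L) * sensors_per_class + seq_len(sensors_per_class))
  })
  n_shared <- round(overlap * sensors_per_class)
  if (n_shared > 0L) {
    for (c in seq(1L, n_classes - 1L, by = 2L)) {
      if (c + 1L > n_classes) break
      # the pair shares the first n_shared sensors of the odd class's block
      blocks[[c + 1L]][seq_len(n_shared)] <- blocks[[c]][seq_len(n_shared)]
    }
  }
  lapply(seq_len(n_classes), function(c) {
    activity_template(paste0("act", c),
                      stats::setNames(rep(activation, length(blocks[[c]])),
                                      blocks[[c]]),
                      count_mean = count_mean[c])
  })
}

#' Default smart-home-like synthetic configuration
#'
#' Emulates the structure of the classic single-resident smart-home
#' benchmark the package's worked examples assume: the 14 sensors of
#' [kasteren_inventory()], 7 activities of daily living with strongly
#' imbalanced frequencies (toileting dominates, dinner preparation is
#' rare), and overlapping kitchen signatures — breakfast and dinner
#' preparation share the fridge, plates cupboard and groceries cupboard,
#' with dinner additionally reaching the freezer and pans cupboard. Sensor
#' occurrence counts vary more for the cooking activities (the fridge may
#' be opened any number of times), which is what makes the numeric
#' encoding noisier than the binary one on this kind of data.
#'
#' @param n Number of instances (default 245, a realistic few weeks of
#'   annotated single-resident data).
#' @param noise Spurious-activation rate (default 0).
#' @return A [synthetic_config()] over the 14-sensor inventory.
#' @export
default_smarthome_config <- function(n = 245L, noise = 0) {
  t <- list(
    activity_template("go-to-bed",
      c("Hall-Bedroom door" = 0.95), count_mean = 1.2, weight = 24),
    activity_template("use-toilet",
      c("Hall-Bathroom door" = 0.9, "Toilet Flush" = 0.9,
        "Hall-Toilet door" = 0.45), count_mean = 1.3, weight = 112),
    activity_template("prepare-breakfast",
      c("Fridge" = 0.9, "Plates cupboard" = 0.8, "Groceries Cupboard" = 0.7,
        "Cups cupboard" = 0.3, "Microwave" = 0.15),
      count_mean = 2.2, weight = 20),
    activity_template("take-shower",
      c("Hall-Bathroom door" = 0.95, "Hall-Toilet door" = 0.25),
      count_mean = 1.3, weight = 23),
    activity_template("get-drink",
      c("Cups cupboard" = 0.9, "Fridge" = 0.7, "Groceries Cupboard" = 0.2),
      count_mean = 1.4, weight = 22),
    activity_template("prepare-dinner",
      c("Fridge" = 0.9, "Plates cupboard" = 0.7, "Groceries Cupboard" = 0.6,
        "Freezer" = 0.8, "Pans Cupboard" = 0.8, "Microwave" = 0.3,
        "Dishwasher" = 0.2), count_mean = 2.8, weight = 10),
    activity_template("leave-house",
      c("Front door" = 0.95), count_mean = 1.1, weight = 34)
  )
  synthetic_config(t, n = n, inventory = kasteren_inventory(), noise = noise)
}
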