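#' Performance metrics from a raw recording
#'
#' The four validated metrics of the subpial-resection assessment model:
#' maximum bipolar force and bleeding rate (safety), mean inter-tip distance
#' and mean bipolar acceleration (movement). Each function takes a
#' [raw_recording()] and returns a scalar in the stated units.
#'
#' @param rec A `voa_recording`.
#' @param instrument `"ua"` (ultrasonic aspirator, dominant hand) or `"bp"`
#'   (bipolar, non-dominant hand).
#' @return A single numeric value.
#' @name metric_functions
NULL

#' @describeIn metric_functions Maximum of the instrument's force trace,
#'   newtons.
#' @export
max_force <- function(rec, instrument = c("bp", "ua")) {
  instrument <- match.arg(instrument)
  f <- rec[[paste0(instrument, "_force")]]
  if (length(f) == 0) stop_input("empty force trace")
  max(f)
}

#' @describeIn metric_functions Net blood volume over net time, mL/s.
#' @export
bleeding_rate <- function(rec) {
  n <- length(rec$t)
  dur <- rec$t[n] - rec$t[1]
  if (!isTRUE(dur > 0)) stop_input("recording duration must be positive")
  (rec$blood_ml[n] - rec$blood_ml[1]) / dur
}

#' @describeIn metric_functions Mean Euclidean distance between the two tips,
#'   millimetres.
#' @export
mean_tip_distance <- function(rec) {
  d <- rec$ua_pos - rec$bp_pos
  if (nrow(d) == 0) stop_input("empty recording")
  mean(sqrt(rowSums(d^2)))
}

#' @describeIn metric_functions Mean magnitude of the central
#'   second-difference acceleration of the tip path, mm/s^2. Endpoints are
#'   dropped; each interior sample uses its local time steps, and a warning
#'   is raised if the sampling interval varies by more than 10%.
#' @export
mean_acceleration <- function(rec, instrument = c("bp", "ua")) {
  instrument <- match.arg(instrument)
  p <- rec[[paste0(instrument, "_pos")]]
  n <- nrow(p)
  if (n < 3) stop_input("mean_acceleration needs at least 3 samples")
  dt <- diff(rec$t)
  if ((max(dt) - min(dt)) / mean(dt) > 0.10) {
    warning("sampling interval varies by more than 10%; ",
            "second differences use per-interval time steps")
  }
  # non-uniform central second difference at sample k (interior):
  # a_k = 2 * (dt1*p[k+1] - (dt1+dt2)*p[k] + dt2*p[k-1]) / (dt1*dt2*(dt1+dt2))
  k <- 2:(n - 1)
  dt1 <- dt[k - 1]; dt2 <- dt[k]
  num <- dt1 * p[k + 1, , drop = FALSE] -
    (dt1 + dt2) * p[k, , drop = FALSE] +
    dt2 * p[k - 1, , drop = FALSE]
  acc <- 2 * num / (dt1 * dt2 * (dt1 + dt2))
  mean(sqrt(rowSums(acc^2)))
}

#' The default metric registry
#'
#' An ordered registry of metric definitions; each entry has a `name`, a
#' human-readable `label`, `units`, a `category` (`safety` or `movement`) and
#' a function of a recording. The default registry holds the four validated
#' metrics; the full candidate space of a metric-development campaign (the
#' reference work screened 270 candidates) is represented by registering
#' additional entries, not by enumerating them here.
#'
#' @return A `voa_registry` (named list of metric definitions).
#' @export
default_metric_registry <- function() {
  metric_registry(
    metric_def("max_force_bipolar", "Max Force w/ Bipolar", "N", "safety",
               function(rec) max_force(rec, "bp")),
    metric_def("bleeding_rate", "Rate of Bleeding", "mL/s", "safety",
               bleeding_rate),
    metric_def("tip_distance_mean", "Instrument Tip Distance", "mm", "movement",
               mean_tip_distance),
    metric_def("acceleration_bipolar", "Acceleration w/ Bipolar", "mm/s^2",
               "movement", function(rec) mean_acceleration(rec, "bp"))
  )
}

#' @rdname default_metric_registry
#' @param name Unique machine name.
#' @param label Display label.
#' @param units Unit string.
#' @param category `"safety"`, `"movement"` or `"other"`.
#' @param fn Function `voa_recording -> numeric(1)`.
#' @export
metric_def <- function(name, label, units, category, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  category <- match.arg(category, c("safety", "movement", "other"))
  structure(list(name = name, label = label, units = units,
                 category = category, fn = fn), class = "voa_metric_def")
}

#' @rdname default_metric_registry
#' @param ... `voa_metric_def` entries, in evaluation order.
#' @export
metric_registry <- function(...) {
  defs <- list(...)
  if (length(defs) == 0) stop_input("registry must contain at least one metric")
  ok <- vapply(defs, inherits, logical(1), "voa_metric_def")
  if (!all(ok)) stop_input("all registry entries must be metric_def objects")
  nms <- vapply(defs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop_input("duplicate metric name in registry: ",
               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(defs) <- nms
  structure(defs, class = "voa_registry")
}

#' Compute the metric vector of one recording
#'
#' @param rec A `voa_recording`.
#' @param registry A `voa_registry`; defaults to the four validated metrics.
#' @return A named numeric vector of class `metric_vector` with `units`,
#'   `categories` and `labels` attributes, in registry order.
#' @export
compute_metric_vector <- function(rec, registry = default_metric_registry()) {
  stopifnot(inherits(registry, "voa_registry"))
  vals <- vapply(registry, function(def) {
    v <- tryCatch(def$fn(rec), error = function(e) {
      stop_input("metric '", def$name, "' failed: ", conditionMessage(e))
    })
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_input("metric '", def$name, "' returned a non-finite value")
    }
    v
  }, numeric(1))
  structure(vals,
            units = vapply(registry, `[[`, character(1), "units"),
            categories = vapply(registry, `[[`, character(1), "category"),
            labels = vapply(registry, `[[`, character(1), "label"),
            class = "metric_vector")
}

#' Extract the cohort metric table
#'
#' Applies the registry to every recording of a cohort (in memory or from a
#' manifest on disk) and returns the labelled metric table used for
#' normalization, training and cross-validation.
#'
#' @param cohort Result of [generate_cohort()], or the path of a manifest CSV
#'   (`trial_id,file,group`) whose recording files sit alongside it.
#' @param registry A `voa_registry`.
#' @return A data.frame `trial_id, group, <metric columns>` with the
#'   registry's `units`/`categories`/`labels` attached as attributes.
#' @export
extract_cohort_metrics <- function(cohort, registry = default_metric_registry()) {
  if (is.character(cohort)) {
    manifest <- utils::read.csv(cohort)
    if (!all(c("trial_id", "file", "group") %in% names(manifest))) {
      stop_input("manifest must have columns trial_id,file,group")
    }
    dir <- dirname(cohort)
    recs <- lapply(file.path(dir, manifest$file), read_recording)
    cohort <- list(recordings = recs, group = manifest$group,
                   trial_id = manifest$trial_id)
  }
  rows <- lapply(cohort$recordings, compute_metric_vector, registry = registry)
  tab <- as.data.frame(do.call(rbind, rows))
  out <- cbind(data.frame(trial_id = cohort$trial_id, group = cohort$group),
               tab)
  attr(out, "units") <- vapply(registry, `[[`, character(1), "units")
  attr(out, "categories") <- vapply(registry, `[[`, character(1), "category")
  attr(out, "labels") <- vapply(registry, `[[`, character(1), "label")
  out
}

#' Write / read a cohort metric table
#'
#' The CSV holds `trial_id,group,<metrics>`; units, categories and labels go
#' to a JSON sidecar (`<path>.meta.json`).
#'
#' @param table Metric table from [extract_cohort_metrics()].
#' @param path CSV path.
#' @return `write_metric_table` returns `path` invisibly; `read_metric_table`
#'   the table with attributes restored when the sidecar exists.
#' @export
write_metric_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  meta <- list(schema_version = "1.0",
               units = as.list(attr(table, "units") %||% list()),
               categories = as.list(attr(table, "categories") %||% list()),
               labels = as.list(attr(table, "labels") %||% list()))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_metric_table
#' @export
read_metric_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  side <- paste0(path, ".meta.json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    attr(tab, "units") <- unlist(meta$units)
    attr(tab, "categories") <- unlist(meta$categories)
    attr(tab, "labels") <- unlist(meta$labels)
  }
  tab
}

# Columns of a metric table that hold metric values.
metric_columns <- function(table) {
  setdiff(names(table), c("trial_id", "group"))
}
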