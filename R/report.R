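#' Build the two-step, mastery-gated feedback report
#'
#' Normalizes a trainee's raw metrics with the model's frozen training
#' parameters, classifies the performance, decomposes the margin into
#' per-metric competency verdicts and groups them into an ordered sequence of
#' steps. Following the mastery-learning model, step 2 unlocks only when the
#' trainee is competent on every step-1 metric; otherwise the scenario must
#' be repeated. By default step 1 holds the safety metrics and step 2 the
#' movement metrics, reflecting that safety takes precedence over movement
#' efficiency.
#'
#' @param model A `voa_model`.
#' @param v Named vector of raw metric values (a `metric_vector`), a
#'   `voa_recording` (metrics are extracted first with `registry`), or a
#'   one-row metric data.frame.
#' @param step_plan Named list of metric-name groups, in step order; must
#'   partition the model's metric set. Default: metrics grouped by category,
#'   safety first.
#' @param registry Registry used when `v` is a recording.
#' @return A `voa_report`: `classification`, `steps` (each with `name`,
#'   `metrics` feedback data.frame, `passed`), `step1_passed`,
#'   `step2_unlocked`, `must_redo`.
#' @export
build_report <- function(model, v, step_plan = NULL,
                         registry = default_metric_registry()) {
  stopifnot(inherits(model, "voa_model"))
  if (inherits(v, "voa_recording")) v <- compute_metric_vector(v, registry)
  if (is.data.frame(v)) {
    if (nrow(v) != 1L) stop_input("metric data.frame must have exactly one row")
    v <- unlist(v[, metric_columns(v), drop = FALSE])
  }
  z <- normalize_metrics(v, model$normalization)
  step_plan <- step_plan %||% default_step_plan(model)
  validate_step_plan(model, step_plan)

  cls <- classify_trainee(model, z)
  fb <- metric_feedback(model, z)
  steps <- lapply(seq_along(step_plan), function(i) {
    m <- fb[match(step_plan[[i]], fb$metric), , drop = FALSE]
    rownames(m) <- NULL
    list(name = names(step_plan)[i], metrics = m, passed = all(m$competent))
  })
  step1_passed <- steps[[1]]$passed
  structure(
    list(classification = cls, steps = steps,
         step1_passed = step1_passed,
         step2_unlocked = step1_passed,
         must_redo = !step1_passed),
    class = "voa_report"
  )
}

default_step_plan <- function(model) {
  cats <- model$categories
  plan <- list()
  for (cat in c("safety", "movement", "other")) {
    if (any(cats == cat)) plan[[cat]] <- model$metric_names[cats == cat]
  }
  if (length(plan) == 0) plan <- list(all = model$metric_names)
  plan
}

validate_step_plan <- function(model, step_plan) {
  if (!is.list(step_plan) || length(step_plan) < 1) {
    stop_input("step_plan must be a non-empty named list of metric groups")
  }
  flat <- unlist(step_plan, use.names = FALSE)
  if (anyDuplicated(flat) || !setequal(flat, model$metric_names)) {
    stop_input("step_plan must partition the model's metric set")
  }
  invisible(TRUE)
}

#' @export
print.voa_report <- function(x, ...) {
  cat("=== Operative performance report ===\n")
  cat(sprintf("Classification: %s  (%.1f%% skilled / %.1f%% novice)\n",
              toupper(x$classification$label),
              100 * x$classification$p_skilled,
              100 * x$classification$p_novice))
  for (i in seq_along(x$steps)) {
    st <- x$steps[[i]]
    cat(sprintf("\nStep %d (%s): %s\n", i, st$name,
                if (st$passed) "passed" else "not passed"))
    for (j in seq_len(nrow(st$metrics))) {
      m <- st$metrics[j, ]
      cat(sprintf("  %-24s z = %+6.2f  contribution %+7.3f  [%s]\n",
                  m$metric, m$z, m$contribution, m$message_key))
    }
    if (i == 1L && !st$passed) {
      cat("  -> competency not reached on all step-1 metrics;",
          "later steps stay locked\n")
    }
  }
  cat(sprintf("\nStep 2 unlocked: %s   Must redo scenario: %s\n",
              x$step2_unlocked, x$must_redo))
  invisible(x)
}

#' Write a feedback report as JSON
#' @param report A `voa_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "voa_report"))
  payload <- list(
    schema_version = "1.0",
    classification = list(
      label = report$classification$label,
      score = report$classification$score,
      p_skilled = report$classification$p_skilled,
      p_novice = report$classification$p_novice
    ),
    steps = lapply(report$steps, function(st) {
      list(name = st$name, passed = st$passed, metrics = st$metrics)
    }),
    step2_unlocked = report$step2_unlocked,
    must_redo = report$must_redo
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Assess a recorded trial end to end
#'
#' Convenience wrapper: read (or take) a recording, extract metrics with the
#' registry, and build the feedback report against a fitted model.
#'
#' @param model A `voa_model` or the path of a model JSON.
#' @param recording A `voa_recording` or the path of a recording CSV.
#' @param step_plan,registry Passed to [build_report()].
#' @return A `voa_report`.
#' @export
assess_recording <- function(model, recording, step_plan = NULL,
                             registry = default_metric_registry()) {
  if (is.character(model)) model <- load_model(model)
  if (is.character(recording)) recording <- read_recording(recording)
  build_report(model, recording, step_plan = step_plan, registry = registry)
}
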