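#' Save / load a fitted model as JSON
#'
#' The JSON carries everything needed to assess a new trainee: metric names,
#' categories, weights, bias, the frozen normalization parameters, the class
#' encoding and training metadata, under a `schema_version` field. Numbers
#' are written at full precision so a round-trip reproduces the model
#' exactly.
#'
#' @param model A `voa_model`.
#' @param path JSON file path.
#' @return `save_model` returns `path` invisibly; `load_model` a `voa_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "voa_model"))
  payload <- list(
    schema_version = model$schema_version,
    metric_names = model$metric_names,
    categories = model$categories,
    weights = unname(model$weights),
    bias = model$bias,
    normalization = list(
      means = unname(model$normalization$means),
      sds = unname(model$normalization$sds)
    ),
    class_encoding = model$class_encoding,
    training_meta = model$training_meta
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_input("model file not found: ", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$schema_version) || !identical(as.character(p$schema_version), "1.0")) {
    stop_input("unsupported model schema_version: ",
               p$schema_version %||% "<missing>")
  }
  required <- c("metric_names", "weights", "bias", "normalization")
  missing <- required[!vapply(required, function(f) !is.null(p[[f]]), logical(1))]
  if (length(missing)) {
    stop_input("model file missing field(s): ", paste(missing, collapse = ", "))
  }
  k <- length(p$metric_names)
  if (length(p$weights) != k) {
    stop_input("model file has ", length(p$weights), " weights for ", k,
               " metrics")
  }
  if (length(p$normalization$means) != k || length(p$normalization$sds) != k) {
    stop_input("normalization parameters do not match the metric list")
  }
  norm <- structure(
    list(means = stats::setNames(as.numeric(p$normalization$means), p$metric_names),
         sds = stats::setNames(as.numeric(p$normalization$sds), p$metric_names)),
    class = "voa_normalizer"
  )
  categories <- p$categories %||% rep("other", k)
  new_voa_model(p$metric_names, p$weights, p$bias, norm, categories,
                training_meta = as.list(p$training_meta %||% list()))
}

#' Published reference weights for the subpial-resection model
#'
#' Loads the shipped reference model holding the published weights of the
#' four validated metrics (bipolar maximum force, bleeding rate, inter-tip
#' distance, bipolar acceleration — all negative, so competency corresponds
#' to values below the training-cohort mean). The original training cohort's
#' means and standard deviations were never published, so the file carries
#' identity normalization (mean 0, sd 1): the model operates directly on
#' z-scores, which is how the proficiency benchmarks are expressed.
#'
#' @return A `voa_model`.
#' @export
reference_model <- function() {
  load_model(system.file("extdata", "subpial_svm_reference.json",
                         package = "voa", mustWork = TRUE))
}
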