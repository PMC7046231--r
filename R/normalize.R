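#' Fit z-score normalization parameters on a training cohort
#'
#' Stores per-metric mean and sample standard deviation (n - 1 denominator).
#' Normalization puts every metric on the same relative scale and anchors the
#' proficiency benchmark: z = 0 is the training-cohort mean.
#'
#' @param table A cohort metric table (data.frame with `trial_id`/`group`
#'   columns ignored) or a numeric matrix/data.frame of metrics only.
#' @return A `voa_normalizer` with `means` and `sds`, both named.
#' @export
fit_normalizer <- function(table) {
  x <- as.data.frame(table)[, metric_columns(as.data.frame(table)), drop = FALSE]
  if (nrow(x) < 2) stop_input("need at least 2 rows to fit a normalizer")
  means <- vapply(x, mean, numeric(1))
  sds <- vapply(x, stats::sd, numeric(1))
  bad <- names(sds)[!is.finite(sds) | sds <= 0]
  if (length(bad)) {
    stop_input("degenerate (constant) metric column: ",
               paste(bad, collapse = ", "))
  }
  structure(list(means = means, sds = sds), class = "voa_normalizer")
}

#' Apply frozen z-score normalization
#'
#' `z = (value - training mean) / training sd`, using the parameters frozen at
#' fit time. New observations must be normalized with the training
#' parameters, never their own.
#'
#' @param x A named numeric vector (`metric_vector`), or a data.frame /
#'   matrix with columns matching the normalizer's metric names.
#' @param params A `voa_normalizer`.
#' @return Object of the same shape holding z-scores.
#' @export
normalize_metrics <- function(x, params) {
  stopifnot(inherits(params, "voa_normalizer"))
  nms <- names(params$means)
  if (is.null(dim(x))) {
    missing <- setdiff(nms, names(x))
    if (length(missing)) {
      stop_input("metric(s) missing from input: ", paste(missing, collapse = ", "))
    }
    z <- (as.numeric(x[nms]) - params$means) / params$sds
    names(z) <- nms
    z
  } else {
    x <- as.data.frame(x)
    missing <- setdiff(nms, names(x))
    if (length(missing)) {
      stop_input("metric(s) missing from input: ", paste(missing, collapse = ", "))
    }
    z <- sweep(as.matrix(x[, nms, drop = FALSE]), 2, params$means, "-")
    sweep(z, 2, params$sds, "/")
  }
}
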