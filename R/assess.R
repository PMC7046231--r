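#' Score, classify and explain a trainee's performance
#'
#' The model output is the linear margin `h = sum_i theta_i * z_i + b`.
#' Because the model is linear, `h` decomposes exactly into per-metric
#' contributions `theta_i * z_i` plus the bias — the basis of the
#' explainable per-metric feedback.
#'
#' @param model A `voa_model`.
#' @param z Named z-score vector matching the model's metrics.
#' @return `score`: the margin `h`.
#' @export
score <- function(model, z) {
  stopifnot(inherits(model, "voa_model"))
  z <- check_z(model, z)
  sum(model$weights * z) + model$bias
}

check_z <- function(model, z) {
  if (is.null(names(z))) {
    if (length(z) != length(model$metric_names)) {
      stop_input("z-vector has ", length(z), " entries; model expects ",
                 length(model$metric_names))
    }
    names(z) <- model$metric_names
  }
  missing <- setdiff(model$metric_names, names(z))
  if (length(missing)) {
    stop_input("z-vector missing metric(s): ", paste(missing, collapse = ", "))
  }
  z <- z[model$metric_names]
  if (any(!is.finite(z))) stop_input("z-scores must be finite")
  z
}

#' @rdname score
#' @param h Model output (margin).
#' @return `classify_score`: `"skilled"` if `h > 0`, else `"novice"`
#'   (`h = 0` fails toward further practice).
#' @export
classify_score <- function(h) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h)) {
    stop_input("model output must be a single finite number")
  }
  if (h > 0) "skilled" else "novice"
}

#' @rdname score
#' @return `class_probabilities`: list with `p_skilled = 1/(1 + exp(-h))`
#'   and `p_novice = 1 - p_skilled`, expressing expertise as a gradient
#'   rather than a binary call.
#' @export
class_probabilities <- function(h) {
  if (any(!is.finite(h))) stop_input("model output must be finite")
  p <- stats::plogis(h)
  list(p_skilled = p, p_novice = stats::plogis(-h))
}

#' Classify a trainee from a z-score vector
#'
#' @param model A `voa_model`.
#' @param z Named z-score vector.
#' @return A `voa_classification`: `score`, `label`, `p_skilled`, `p_novice`.
#' @export
classify_trainee <- function(model, z) {
  h <- score(model, z)
  p <- class_probabilities(h)
  structure(list(score = h, label = classify_score(h),
                 p_skilled = p$p_skilled, p_novice = p$p_novice),
            class = "voa_classification")
}

#' @export
print.voa_classification <- function(x, ...) {
  cat(sprintf("%s (%.1f%% skilled / %.1f%% novice), margin %.4f\n",
              x$label, 100 * x$p_skilled, 100 * x$p_novice, x$score))
  invisible(x)
}

#' Per-metric competency verdicts
#'
#' A metric's contribution to the margin is `theta_i * z_i`; the trainee is
#' competent on a metric when the contribution is strictly positive, i.e.
#' when the metric pushes the decision toward "skilled". With a negative
#' weight this means performing below the training-cohort mean (z < 0); the
#' proficiency benchmark boundary z = 0 itself counts as not yet competent.
#' The bias is a weight without a corresponding metric: it shifts the
#' decision boundary and the probabilities but carries no metric-wise
#' verdict.
#'
#' @param model A `voa_model`.
#' @param z Named z-score vector.
#' @return Data.frame with one row per metric: `metric`, `category`, `z`,
#'   `weight`, `contribution`, `competent`, `message_key`
#'   (`reinforce`/`improve`).
#' @export
metric_feedback <- function(model, z) {
  z <- check_z(model, z)
  contribution <- unname(model$weights * z)
  competent <- contribution > 0
  data.frame(
    metric = model$metric_names,
    category = model$categories,
    z = unname(z),
    weight = unname(model$weights),
    contribution = contribution,
    competent = competent,
    message_key = ifelse(competent, "reinforce", "improve")
  )
}

#' Rank metrics by importance
#'
#' A metric whose weight has larger magnitude plays a greater role in the
#' decision; metrics are ordered by `|weight|` descending, ties broken by
#' model order.
#'
#' @param model A `voa_model`.
#' @return Character vector of metric names, most important first.
#' @export
rank_metrics <- function(model) {
  stopifnot(inherits(model, "voa_model"))
  model$metric_names[order(-abs(model$weights),
                           seq_along(model$weights))]
}
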