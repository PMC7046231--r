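#' Linear SVM training by monotone iterative cost reduction
#'
#' Minimizes the L2-regularized hinge cost
#' `J(theta, b) = 1/2 ||theta||^2 + C * sum_i max(0, 1 - y_i (theta.z_i + b))`
#' by deterministic subgradient descent with backtracking step halving: a
#' step is only taken if it reduces the cost, so the cost trajectory is
#' non-increasing by construction. Initialization is at the origin, which
#' makes the fit exactly antisymmetric under label flips.
#'
#' @param Z Numeric matrix of z-scored metrics, one row per participant.
#' @param y Labels coded +1 (skilled) / -1 (novice).
#' @param C Hinge cost weight (regularization trade-off).
#' @param max_iter Iteration budget.
#' @param tol Relative-improvement convergence tolerance.
#' @return List with `weights`, `bias`, `objective` (cost after each accepted
#'   iteration, starting with the initial cost), `iterations`, `converged`.
#' @keywords internal
svm_hinge_fit <- function(Z, y, C = 1, max_iter = 500L, tol = 1e-9) {
  Z <- as.matrix(Z)
  storage.mode(Z) <- "double"
  n <- nrow(Z); k <- ncol(Z)
  if (length(y) != n) stop_input("labels must match rows of Z")
  if (!all(y %in% c(-1, 1))) stop_input("labels must be coded +1 / -1")
  if (length(unique(y)) < 2) stop_input("training needs both classes present")
  if (any(!is.finite(Z))) stop_input("Z must be finite")

  obj <- function(w, b) {
    m <- 1 - y * (drop(Z %*% w) + b)
    0.5 * sum(w^2) + C * sum(pmax(0, m))
  }
  w <- numeric(k); b <- 0
  J <- obj(w, b)
  trace <- numeric(max_iter + 1L); trace[1L] <- J
  eta <- 1 / (1 + C)
  stalls <- 0L; flat <- 0L; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    margin <- 1 - y * (drop(Z %*% w) + b)
    act <- margin > 0
    gw <- w - C * drop(crossprod(Z[act, , drop = FALSE], y[act]))
    gb <- -C * sum(y[act])
    gnorm2 <- sum(gw^2) + gb^2
    if (gnorm2 < 1e-24) { trace[it + 1L] <- J; it_converged <- TRUE; break }
    step <- eta
    accepted <- FALSE
    for (h in 1:40) {
      w2 <- w - step * gw; b2 <- b - step * gb
      J2 <- obj(w2, b2)
      if (J2 < J) {
        flat <- if (J - J2 < tol * (1 + J)) flat + 1L else 0L
        w <- w2; b <- b2; J <- J2
        eta <- min(step * 1.5, 1 / (1 + C))
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    trace[it + 1L] <- J
    if (!accepted) {
      stalls <- stalls + 1L
      eta <- eta / 2
      if (stalls >= 20L) break
    } else if (flat >= 10L) break
  }
  list(weights = w, bias = b, objective = trace[seq_len(it + 1L)],
       iterations = it, converged = it < max_iter)
}

CLASS_ENCODING <- c(skilled = 1, novice = -1)

encode_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), names(CLASS_ENCODING))
  if (length(bad)) {
    stop_input("unknown group label(s): ", paste(bad, collapse = ", "),
               " (expected skilled/novice)")
  }
  unname(CLASS_ENCODING[labels])
}

new_voa_model <- function(metric_names, weights, bias, normalization,
                          categories, training_meta = list()) {
  stopifnot(length(weights) == length(metric_names),
            length(categories) == length(metric_names))
  structure(
    list(schema_version = "1.0",
         metric_names = as.character(metric_names),
         categories = as.character(categories),
         weights = stats::setNames(as.numeric(weights), metric_names),
         bias = as.numeric(bias),
         normalization = normalization,
         class_encoding = as.list(CLASS_ENCODING),
         training_meta = training_meta),
    class = "voa_model"
  )
}

#' Fit the skill-classification model on a labelled cohort
#'
#' The central fitting function: freezes z-score normalization parameters on
#' the training cohort, trains a linear SVM on the z-scores by monotone
#' iterative cost reduction, and returns a self-contained model object
#' holding metric names, categories, weights, bias and the frozen
#' normalization — everything needed to assess a new trainee.
#'
#' @param table Cohort metric table (`trial_id,group,<metrics>` data.frame) or
#'   a numeric matrix/data.frame of raw metrics.
#' @param labels Group labels (`skilled`/`novice`); taken from the table's
#'   `group` column when present.
#' @param C Hinge cost weight; larger values penalize margin violations more.
#' @param iterations Training iteration budget.
#' @param seed Stored for provenance; the solver itself is deterministic.
#' @param categories Per-metric category (`safety`/`movement`/`other`);
#'   defaults to the table's `categories` attribute, else `other`.
#' @return A `voa_model`.
#' @seealso [predict.voa_model()], [loocv()], [select_metrics()],
#'   [build_report()]
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_skilled = 10, n_novice = 10, seed = 1))
#' tab <- extract_cohort_metrics(cohort)
#' fit <- voa_fit(tab)
#' coef(fit)
#' @export
voa_fit <- function(table, labels = NULL, C = 1, iterations = 500L,
                    seed = 1L, categories = NULL) {
  df <- as.data.frame(table)
  if (is.null(labels)) {
    if (!"group" %in% names(df)) stop_input("no `labels` and no `group` column")
    labels <- df$group
  }
  y <- encode_labels(labels)
  cols <- metric_columns(df)
  norm <- fit_normalizer(df)
  Z <- normalize_metrics(df, norm)
  fit <- svm_hinge_fit(Z, y, C = C, max_iter = as.integer(iterations))
  if (is.null(categories)) {
    categories <- attr(table, "categories")[cols] %||% rep("other", length(cols))
  }
  new_voa_model(
    metric_names = cols, weights = fit$weights, bias = fit$bias,
    normalization = norm, categories = categories,
    training_meta = list(C = C, iterations = fit$iterations,
                         seed = as.integer(seed),
                         final_cost = fit$objective[length(fit$objective)],
                         objective = fit$objective,
                         n = nrow(Z))
  )
}

#' @export
print.voa_model <- function(x, ...) {
  cat("Linear skill-classification model (", length(x$weights),
      " metrics)\n", sep = "")
  cat(sprintf("  decision: h = sum(theta_i * z_i) + b,  b = %.4f\n", x$bias))
  w <- format(round(x$weights, 4))
  for (i in seq_along(w)) {
    cat(sprintf("  %-24s [%s] %10s\n", x$metric_names[i], x$categories[i], w[i]))
  }
  cat("  h > 0 -> skilled, h <= 0 -> novice\n")
  invisible(x)
}

#' @export
coef.voa_model <- function(object, ...) {
  c(object$weights, bias = object$bias)
}

#' @export
summary.voa_model <- function(object, ...) {
  rank_order <- rank_metrics(object)
  df <- data.frame(
    metric = object$metric_names,
    category = object$categories,
    weight = unname(object$weights),
    importance_rank = match(object$metric_names, rank_order),
    train_mean = unname(object$normalization$means[object$metric_names]),
    train_sd = unname(object$normalization$sds[object$metric_names])
  )
  structure(list(metrics = df, bias = object$bias,
                 training_meta = object$training_meta),
            class = "summary.voa_model")
}

#' @export
print.summary.voa_model <- function(x, ...) {
  cat("Model summary\n")
  print(x$metrics, row.names = FALSE)
  cat(sprintf("bias: %.4f\n", x$bias))
  if (!is.null(x$training_meta$C)) {
    cat(sprintf("trained with C = %g, %d iterations, final cost %.6g\n",
                x$training_meta$C, x$training_meta$iterations,
                x$training_meta$final_cost))
  }
  invisible(x)
}

#' Classify new observations with a fitted model
#'
#' Raw metric values are z-scored with the model's frozen training
#' parameters, then scored as `h = sum(theta_i z_i) + b`. `h > 0` classifies
#' as skilled, `h <= 0` as novice (ambiguous performance fails toward
#' further practice); class probabilities are the logistic transform of `h`.
#'
#' @param object A `voa_model`.
#' @param newdata Metric table (data.frame/matrix) or a single named vector
#'   of raw metric values.
#' @param type `"label"`, `"score"` or `"prob"`.
#' @param ... Unused.
#' @return Labels, scores, or a two-column probability matrix.
#' @export
predict.voa_model <- function(object, newdata,
                              type = c("label", "score", "prob"), ...) {
  type <- match.arg(type)
  z <- normalize_metrics(newdata, object$normalization)
  if (is.null(dim(z))) z <- matrix(z, 1L, dimnames = list(NULL, names(z)))
  h <- drop(z[, object$metric_names, drop = FALSE] %*% object$weights) +
    object$bias
  switch(type,
         score = h,
         label = vapply(h, classify_score, character(1)),
         prob = {
           p <- class_probabilities(h)
           cbind(p_skilled = p$p_skilled, p_novice = p$p_novice)
         })
}
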