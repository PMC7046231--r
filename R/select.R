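#' Combined forward/backward wrapper metric selection
#'
#' Wrapper search over metric subsets scored by leave-one-out
#' cross-validation accuracy. The forward phase repeatedly adds the candidate
#' metric that maximizes LOOCV accuracy, stopping when no addition improves
#' it; the backward phase repeatedly drops any metric whose removal does not
#' decrease accuracy; the two phases alternate until a full pass changes
#' nothing. Ties are broken toward the smaller set, then by candidate order.
#'
#' @param table Cohort metric table or numeric metric matrix.
#' @param labels Group labels; taken from the `group` column when present.
#' @param C,iterations Trainer settings for the inner cross-validations.
#' @param max_metrics Optional cap on the selected-set size.
#' @return A `voa_selection` with `selected` (metric names), `accuracy`
#'   (percent) and `trace` (a data.frame logging every evaluated set).
#' @export
select_metrics <- function(table, labels = NULL, C = 1, iterations = 300L,
                           max_metrics = Inf) {
  df <- as.data.frame(table)
  if (is.null(labels)) {
    if (!"group" %in% names(df)) stop_input("no `labels` and no `group` column")
    labels <- df$group
  }
  labels <- as.character(labels)
  candidates <- metric_columns(df)
  if (length(candidates) < 1) stop_input("empty candidate metric set")
  x <- df[, candidates, drop = FALSE]

  trace <- list()
  evaluate <- function(set, phase) {
    acc <- loocv(x[, set, drop = FALSE], labels,
                 C = C, iterations = iterations)$accuracy
    trace[[length(trace) + 1L]] <<- data.frame(
      phase = phase, metrics = paste(set, collapse = "+"),
      size = length(set), accuracy = acc
    )
    acc
  }

  selected <- character(0)
  best_acc <- -Inf
  repeat {
    changed <- FALSE
    # forward: add the best-improving candidate until none improves
    repeat {
      pool <- setdiff(candidates, selected)
      if (!length(pool) || length(selected) >= max_metrics) break
      accs <- vapply(pool, function(m) evaluate(c(selected, m), "forward"),
                     numeric(1))
      best <- which.max(accs)  # ties -> earliest in candidate order
      if (accs[best] > best_acc) {
        selected <- c(selected, pool[best])
        best_acc <- unname(accs[best])
        changed <- TRUE
      } else break
    }
    # backward: drop any metric whose removal does not hurt
    repeat {
      if (length(selected) < 2) break
      accs <- vapply(seq_along(selected), function(i) {
        evaluate(selected[-i], "backward")
      }, numeric(1))
      droppable <- which(accs >= best_acc)
      if (!length(droppable)) break
      # prefer the drop with the highest accuracy; ties -> earliest
      best <- droppable[which.max(accs[droppable])]
      selected <- selected[-best]
      best_acc <- max(unname(accs[best]), best_acc)
      changed <- TRUE
    }
    if (!changed) break
  }
  structure(
    list(selected = selected, accuracy = best_acc,
         trace = do.call(rbind, trace)),
    class = "voa_selection"
  )
}

#' @export
print.voa_selection <- function(x, ...) {
  cat("Wrapper metric selection (forward/backward, LOOCV accuracy)\n")
  cat(sprintf("  selected (%d): %s\n", length(x$selected),
              paste(x$selected, collapse = ", ")))
  cat(sprintf("  LOOCV accuracy %.1f%%  (%d candidate sets evaluated)\n",
              x$accuracy, nrow(x$trace)))
  invisible(x)
}

#' Save a selection trace as JSON
#' @param sel A `voa_selection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path) {
  jsonlite::write_json(
    list(schema_version = "1.0", selected = sel$selected,
         accuracy = sel$accuracy, trace = sel$trace),
    path, auto_unbox = TRUE, digits = I(17)
  )
  invisible(path)
}
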