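#' Confusion counts and derived rates
#'
#' Builds a cross-validation result from raw confusion counts. Sensitivity is
#' defined on the skilled class (skilled correctly classified / skilled
#' total) and specificity on the novice class, matching the convention in
#' which a cohort with every skilled member correct reports 100% sensitivity.
#' Rates are percentages.
#'
#' @param skilled_correct,skilled_total Skilled members correctly classified
#'   and total.
#' @param novice_correct,novice_total Same for the novice class.
#' @return A `voa_cv` object with fields `counts` (2x2 confusion matrix,
#'   truth in rows), `accuracy`, `sensitivity`, `specificity` (percent).
#' @export
cv_result <- function(skilled_correct, skilled_total,
                      novice_correct, novice_total) {
  stopifnot(skilled_correct <= skilled_total, novice_correct <= novice_total,
            skilled_correct >= 0, novice_correct >= 0)
  counts <- matrix(
    c(skilled_correct, skilled_total - skilled_correct,
      novice_total - novice_correct, novice_correct),
    2, 2, byrow = TRUE,
    dimnames = list(truth = c("skilled", "novice"),
                    predicted = c("skilled", "novice"))
  )
  n <- skilled_total + novice_total
  structure(
    list(counts = counts,
         accuracy = 100 * (skilled_correct + novice_correct) / n,
         sensitivity = 100 * skilled_correct / skilled_total,
         specificity = 100 * novice_correct / novice_total,
         n = n),
    class = "voa_cv"
  )
}

#' @export
print.voa_cv <- function(x, ...) {
  cat("Leave-one-out cross-validation\n")
  print(x$counts)
  cat(sprintf("accuracy %.1f%%  sensitivity %.1f%%  specificity %.1f%%  (n = %d)\n",
              x$accuracy, x$sensitivity, x$specificity, x$n))
  invisible(x)
}

#' Leave-one-out cross-validation of the skill classifier
#'
#' For each cohort member, the normalizer and SVM are refit on the other
#' n - 1 members and the held-out member is classified; normalization is
#' refit inside every fold so the held-out member never influences the
#' parameters used to score it.
#'
#' @param table Cohort metric table or numeric metric matrix.
#' @param labels Group labels; taken from the `group` column when present.
#' @param C,iterations Trainer settings passed to [voa_fit()].
#' @return A `voa_cv`, with the per-member predictions in `$predictions`.
#' @export
loocv <- function(table, labels = NULL, C = 1, iterations = 500L) {
  df <- as.data.frame(table)
  if (is.null(labels)) {
    if (!"group" %in% names(df)) stop_input("no `labels` and no `group` column")
    labels <- df$group
  }
  labels <- as.character(labels)
  n <- nrow(df)
  if (n < 3) stop_input("leave-one-out needs at least 3 members")
  encode_labels(labels)  # validates label values
  if (length(unique(labels)) < 2) stop_input("both classes must be present")
  cols <- metric_columns(df)
  x <- df[, cols, drop = FALSE]
  pred <- character(n)
  for (i in seq_len(n)) {
    train_lab <- labels[-i]
    if (length(unique(train_lab)) < 2) {
      stop_input("fold ", i, ": training set contains a single class")
    }
    fit <- voa_fit(x[-i, , drop = FALSE], labels = train_lab,
                   C = C, iterations = iterations)
    pred[i] <- predict(fit, x[i, , drop = FALSE], type = "label")
  }
  res <- cv_result(
    skilled_correct = sum(pred == "skilled" & labels == "skilled"),
    skilled_total = sum(labels == "skilled"),
    novice_correct = sum(pred == "novice" & labels == "novice"),
    novice_total = sum(labels == "novice")
  )
  res$predictions <- data.frame(truth = labels, predicted = pred)
  res
}
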