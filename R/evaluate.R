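#' Unweighted mean of per-weight-class accuracies
#'
#' The headline accuracy of an evaluation is the unweighted arithmetic
#' mean of the per-weight-class accuracies, rounded to two decimals --
#' e.g. groups at 90, 85.83 and 88.33 percent average to 88.05.
#'
#' @param accuracies Numeric vector of per-group accuracies (percent).
#' @return Mean accuracy in percent, rounded to 2 decimals.
#' @export
weight_class_average <- function(accuracies) {
  if (length(accuracies) == 0L || anyNA(accuracies))
    stop("weight_class_average: need non-missing accuracies", call. = FALSE)
  round(mean(accuracies), 2L)
}

#' Evaluate the classifier on a labelled dataset
#'
#' Classifies every recording end to end and tabulates a six-class
#' confusion matrix, per-class accuracies, per-weight-class accuracies,
#' the overall accuracy (trace over total) and the average of the
#' per-weight-class accuracies.
#'
#' @param ds A `synthetic_dataset`, or any list of recordings with
#'   `pressure`, `thermal` and `truth$label` / `truth$weight_class`.
#' @param model A `reference_model`; defaults to
#'   [default_reference_model()].
#' @param cfg A [run_config()].
#' @return An object of class `evaluation_report`: `confusion` (6 x 6
#'   matrix, rows = truth), `per_class_pct`, `per_weight_pct`,
#'   `overall_pct`, `weight_average_pct`, `n`.
#' @export
evaluate_dataset <- function(ds, model = NULL, cfg = run_config()) {
  if (is.null(model)) model <- default_reference_model(cfg)
  recs <- ds$recordings
  n <- length(recs)
  if (n == 0L) stop("evaluate_dataset: empty dataset", call. = FALSE)

  truth <- character(n)
  pred <- character(n)
  wc <- character(n)
  for (i in seq_len(n)) {
    truth[i] <- recs[[i]]$truth$label
    wc[i] <- recs[[i]]$truth$weight_class %||% "unknown"
    pred[i] <- classify_recording(recs[[i]]$pressure, recs[[i]]$thermal,
                                  model, cfg)$label
  }
  confusion <- table(factor(truth, levels = SLEEP_POSTURES),
                     factor(pred, levels = SLEEP_POSTURES))
  confusion <- unclass(confusion)
  names(dimnames(confusion)) <- c("truth", "predicted")

  correct <- truth == pred
  per_class <- vapply(SLEEP_POSTURES, function(cl) {
    idx <- truth == cl
    if (!any(idx)) NA_real_ else 100 * mean(correct[idx])
  }, numeric(1L))
  weight_levels <- unique(wc)
  per_weight <- vapply(weight_levels, function(w)
    100 * mean(correct[wc == w]), numeric(1L))

  structure(
    list(confusion = confusion,
         per_class_pct = per_class,
         per_weight_pct = per_weight,
         overall_pct = 100 * sum(diag(confusion)) / n,
         weight_average_pct = weight_class_average(per_weight),
         n = n),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d recording(s)\n", x$n))
  cat(sprintf("overall accuracy: %.2f%%\n", x$overall_pct))
  for (w in names(x$per_weight_pct))
    cat(sprintf("  %-7s %.2f%%\n", w, x$per_weight_pct[w]))
  cat(sprintf("weight-class average: %.2f%%\n", x$weight_average_pct))
  cat("confusion matrix (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' @export
#' @rdname evaluate_dataset
#' @param x An `evaluation_report`.
report_to_list <- function(x) {
  list(n = x$n,
       overall_pct = x$overall_pct,
       per_class_pct = as.list(x$per_class_pct),
       per_weight_pct = as.list(x$per_weight_pct),
       weight_average_pct = x$weight_average_pct,
       confusion = x$confusion)
}
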