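#' Confusion matrix and accuracies
#'
#' @param predicted Predicted class labels.
#' @param truth True class labels, same length.
#' @return An object of class `confusion_report`: list with `confusion`
#'   (true x predicted counts), `overall_accuracy` (%), and
#'   `per_class_accuracy` (% correctly identified waveforms per true
#'   class).
#' @export
confusion_report <- function(predicted, truth) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  stopifnot(length(predicted) == length(truth), length(truth) > 0)
  if (!length(intersect(unique(predicted), unique(truth))))
    stop("predicted and true class sets do not overlap")
  classes <- sort(union(unique(predicted), unique(truth)))
  cm <- table(truth = factor(truth, classes),
              predicted = factor(predicted, classes))
  per_class <- 100 * diag(cm) / rowSums(cm)
  structure(list(confusion = cm,
                 overall_accuracy = 100 * sum(diag(cm)) / sum(cm),
                 per_class_accuracy = per_class),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  print(x$confusion)
  cat(sprintf("overall accuracy: %.1f%%\n", x$overall_accuracy))
  invisible(x)
}

#' One-vs-rest ROC curve and AUC
#'
#' Sweeps the decision threshold over the observed score values (each
#' unique value is one step, so ties are handled jointly), computing the
#' true- and false-positive rates of "score >= threshold" calls for the
#' given positive class; the AUC is the trapezoid-rule area under the
#' resulting curve. The AUC is invariant under strictly monotone transforms
#' of the scores.
#'
#' @param scores Numeric scores in `[0, 1]` (e.g. vote fractions for
#'   `positive_class`).
#' @param truth True class labels.
#' @param positive_class The class treated as positive.
#' @return List with `points` (data.frame `threshold, fpr, tpr`) and `auc`.
#' @export
roc_auc <- function(scores, truth, positive_class) {
  stopifnot(length(scores) == length(truth),
            all(scores >= 0 & scores <= 1))
  pos <- as.character(truth) == positive_class
  if (!any(pos) || all(pos))
    stop("need both positive and negative examples")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  idx <- which(!duplicated(s, fromLast = TRUE))  # last index per tied value
  tp <- cumsum(p)[idx]; fp <- cumsum(!p)[idx]
  tpr <- c(0, tp / sum(pos)); fpr <- c(0, fp / sum(!pos))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(points = data.frame(threshold = c(Inf, s[idx]), fpr = fpr,
                           tpr = tpr),
       auc = auc)
}

#' Treatment-effect statistics on waveform metrics
#'
#' Pairwise two-sample Student (pooled-variance) t-tests per metric across
#' condition pairs, plus per-metric one-way ANOVA with post-hoc Tukey HSD.
#' No multiple-testing correction is applied beyond Tukey's.
#'
#' @param table A `feature_table` (or any data.frame with a `label` column
#'   and the value columns).
#' @param values Value columns to test (default: the five metrics present).
#' @param alpha Significance level (default 0.05).
#' @param var_equal Use the pooled-variance t-test (default TRUE; FALSE
#'   gives Welch).
#' @return List with `t_tests` (metric, comparison, statistic, df,
#'   p_value, significant), `anova` (metric, F, p_value, significant) and
#'   `tukey` (metric, comparison, diff, p_adj, significant).
#' @export
group_stats <- function(table, values = NULL, alpha = 0.05,
                        var_equal = TRUE) {
  stopifnot("label" %in% names(table))
  if (is.null(values)) values <- feature_cols(table)
  stopifnot(length(values) >= 1)
  groups <- sort(unique(as.character(table$label)))
  if (length(groups) < 2) stop("need at least 2 groups")
  pairs <- combn(groups, 2, simplify = FALSE)
  tt <- list(); av <- list(); tk <- list()
  for (v in values) {
    for (pr in pairs) {
      a <- table[[v]][table$label == pr[1]]
      b <- table[[v]][table$label == pr[2]]
      ts <- t.test(a, b, var.equal = var_equal)
      tt[[length(tt) + 1L]] <- data.frame(
        metric = v, comparison = paste(pr, collapse = " vs "),
        statistic = unname(ts$statistic), df = unname(ts$parameter),
        p_value = ts$p.value, significant = ts$p.value < alpha,
        stringsAsFactors = FALSE)
    }
    fit <- aov(stats::reformulate("g", v),
               data = data.frame(setNames(list(table[[v]]), v),
                                 g = factor(table$label)))
    an <- summary(fit)[[1]]
    av[[length(av) + 1L]] <- data.frame(
      metric = v, F = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
      significant = isTRUE(an[["Pr(>F)"]][1] < alpha),
      stringsAsFactors = FALSE)
    th <- TukeyHSD(fit)$g
    tk[[length(tk) + 1L]] <- data.frame(
      metric = v, comparison = rownames(th), diff = th[, "diff"],
      p_adj = th[, "p adj"], significant = th[, "p adj"] < alpha,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  list(t_tests = do.call(rbind, tt), anova = do.call(rbind, av),
       tukey = do.call(rbind, tk))
}

#' Full classifier evaluation report
#'
#' Combines the confusion matrix, per-class one-vs-rest ROC/AUC from the
#' vote-fraction scores, the mean score assigned to each class within each
#' true class, and (when recording IDs are available) the recording-level
#' accuracy after majority-vote aggregation.
#'
#' @param predictions A `prediction_set` with `truth` labels.
#' @param truth Optional true labels overriding `predictions$truth`.
#' @param recording_truth Optional named vector mapping recording IDs to
#'   true labels (defaults to the modal truth label per recording).
#' @return List of class `eval_report` with components `confusion`,
#'   `auc` (named per class), `roc` (per-class curves), `mean_scores`
#'   (true class x scored class), `recording` (data.frame plus
#'   `recording_accuracy` %), `n`.
#' @export
evaluate_predictions <- function(predictions, truth = NULL,
                                 recording_truth = NULL) {
  stopifnot(inherits(predictions, "prediction_set"))
  if (is.null(truth)) truth <- predictions$truth
  if (is.null(truth)) stop("true labels required")
  cm <- confusion_report(predictions$predicted, truth)
  classes <- predictions$classes
  roc <- list(); auc <- setNames(numeric(0), character(0))
  for (cl in intersect(classes, unique(truth))) {
    r <- roc_auc(predictions$scores[, cl], truth, cl)
    roc[[cl]] <- r$points
    auc[cl] <- r$auc
  }
  ms <- t(vapply(intersect(classes, unique(truth)), function(tc)
    colMeans(predictions$scores[truth == tc, , drop = FALSE]),
    numeric(length(classes))))
  rec <- NULL; rec_acc <- NA_real_
  if (!is.null(predictions$recording_id)) {
    agg <- aggregate_recording(predictions)
    if (is.null(recording_truth)) {
      recording_truth <- vapply(agg$recording_id, function(r) {
        tt <- truth[predictions$recording_id == r]
        names(which.max(table(tt)))
      }, character(1))
    }
    agg$truth <- recording_truth[agg$recording_id]
    rec <- agg
    rec_acc <- 100 * mean(agg$predicted == agg$truth)
  }
  structure(list(confusion = cm, auc = auc, roc = roc, mean_scores = ms,
                 recording = rec, recording_accuracy = rec_acc,
                 n = length(truth)),
            class = "eval_report")
}

#' Write an evaluation report as JSON plus readable text
#'
#' @param report An `eval_report` from [evaluate_predictions()].
#' @param path Output path without extension; `<path>.json` and
#'   `<path>.txt` are written.
#' @return The two paths, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  cm <- report$confusion
  obj <- list(
    n = report$n,
    confusion = as.data.frame.matrix(unclass(cm$confusion)),
    overall_accuracy = cm$overall_accuracy,
    per_class_accuracy = as.list(cm$per_class_accuracy),
    auc = as.list(report$auc),
    mean_scores = as.data.frame.matrix(report$mean_scores),
    recording_accuracy = report$recording_accuracy,
    note = "no multiple-testing correction applied beyond Tukey HSD")
  jsonlite::write_json(obj, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  txt <- c(utils::capture.output(print(report)),
           sprintf("n = %d waveforms", report$n))
  writeLines(txt, paste0(path, ".txt"))
  invisible(c(paste0(path, ".json"), paste0(path, ".txt")))
}

#' @export
print.eval_report <- function(x, ...) {
  print(x$confusion)
  if (length(x$auc))
    cat("AUC:", paste(sprintf("%s=%.3f", names(x$auc), x$auc),
                      collapse = ", "), "\n")
  if (!is.na(x$recording_accuracy))
    cat(sprintf("recording-level accuracy: %.1f%% (%d recordings)\n",
                x$recording_accuracy, nrow(x$recording)))
  invisible(x)
}
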