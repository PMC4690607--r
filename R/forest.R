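feature_cols <- function(table) {
  intersect(c("h_max", "m_up", "m_down", "w", "h_plateau"), names(table))
}

#' Stratified train/validation split
#'
#' Samples, per class, `round(fraction * class count)` rows (or an
#' explicitly requested count) without replacement into the training set;
#' the remainder is the validation ("unknown") set. Train and validation
#' are disjoint and their union is the input.
#'
#' @param table A `feature_table` with a `label` column.
#' @param fraction Training fraction per class (default 0.33).
#' @param counts Optional named integer vector of per-class training counts
#'   overriding `fraction`.
#' @param seed Optional integer seed for the row sampling.
#' @return List with `train` and `validation` feature tables.
#' @export
stratified_split <- function(table, fraction = 0.33, counts = NULL,
                             seed = NULL) {
  stopifnot(fraction > 0, fraction < 1, "label" %in% names(table))
  if (!is.null(seed)) set.seed(seed)
  classes <- unique(table$label)
  idx_train <- integer(0)
  for (cl in classes) {
    rows <- which(table$label == cl)
    if (length(rows) < 2L) stop("class '", cl, "' has fewer than 2 rows")
    k <- if (!is.null(counts)) {
      if (is.null(counts[[cl]])) stop("no training count given for ", cl)
      as.integer(counts[[cl]])
    } else as.integer(round(fraction * length(rows)))
    if (k > length(rows)) stop("training count exceeds class total for ", cl)
    idx_train <- c(idx_train, sample(rows, k))
  }
  idx_train <- sort(idx_train)
  out <- list(train = table[idx_train, , drop = FALSE],
              validation = table[-idx_train, , drop = FALSE])
  for (i in 1:2) {
    rownames(out[[i]]) <- NULL
    class(out[[i]]) <- c("feature_table", "data.frame")
  }
  out
}

# per-tree OOB error of a fitted randomForest, optionally with one feature
# permuted within each tree's OOB rows
oob_tree_errors <- function(rf, x, y, inbag, permute = NULL) {
  ntree <- ncol(inbag)
  errs <- rep(NA_real_, ntree)
  for (tr in seq_len(ntree)) {
    oob <- which(inbag[, tr] == 0L)
    if (!length(oob)) next
    xo <- x[oob, , drop = FALSE]
    if (!is.null(permute))
      xo[[permute]] <- xo[[permute]][sample.int(length(oob))]
    pred <- predict(rf, xo, predict.all = TRUE)$individual[, tr]
    errs[tr] <- mean(pred != as.character(y[oob]))
  }
  errs
}

#' Train the bagged decision-tree classifier
#'
#' Grows `n_trees` fully developed CART trees (minimum node size 1, Gini
#' impurity), each on a bootstrap resample of the training rows, with
#' `ceiling(sqrt(p))` randomly chosen candidate features per split. The
#' returned model carries the cumulative out-of-bag (OOB) error curve over
#' 1..`n_trees` trees and a standardized permutation importance per
#' feature: the mean over trees of the increase in that tree's OOB error
#' after permuting the feature within its OOB rows, divided by the
#' across-tree standard deviation of those increases (so the conventional
#' "importance < 1" reduction threshold applies).
#'
#' @param train Training `feature_table` (needs >= 2 classes, >= 10 rows).
#' @param n_trees Number of trees (default 50).
#' @param mtry Candidate features per split; default `ceiling(sqrt(p))`.
#' @param seed Integer seed controlling bootstrap and split randomness.
#' @param features Feature columns to use (default: the five metrics
#'   present in the table).
#' @return An object of class `wave_forest`: list with the fitted ensemble
#'   (`rf`), `oob_error` curve, standardized `importance`, `oob_scores`
#'   (per-training-row OOB vote fractions), `classes`, `features`,
#'   `n_trees`, `mtry`, `seed`.
#' @export
train_forest <- function(train, n_trees = 50, mtry = NULL, seed = NULL,
                         features = NULL) {
  if (is.null(features)) features <- feature_cols(train)
  stopifnot(length(features) >= 1, all(features %in% names(train)))
  if (nrow(train) < 10) stop("need at least 10 training rows")
  y <- factor(train$label)
  if (nlevels(y) < 2) stop("training data has a single class")
  x <- as.data.frame(train)[, features, drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mtry)) mtry <- ceiling(sqrt(length(features)))
  rf <- randomForest::randomForest(
    x = x, y = y, ntree = n_trees, mtry = min(mtry, length(features)),
    nodesize = 1, importance = FALSE, keep.forest = TRUE,
    keep.inbag = TRUE)
  base_err <- oob_tree_errors(rf, x, y, rf$inbag)
  imp <- vapply(features, function(f) {
    perm_err <- oob_tree_errors(rf, x, y, rf$inbag, permute = f)
    d <- perm_err - base_err
    d <- d[is.finite(d)]
    s <- sd(d)
    if (!is.finite(s) || s < 1e-12) 0 else mean(d) / s
  }, numeric(1))
  structure(list(rf = rf, oob_error = unname(rf$err.rate[, "OOB"]),
                 importance = imp, oob_scores = rf$votes,
                 classes = levels(y), features = features,
                 n_trees = n_trees, mtry = min(mtry, length(features)),
                 seed = seed),
            class = "wave_forest")
}

#' @export
print.wave_forest <- function(x, ...) {
  cat(sprintf("wave_forest: %d trees, mtry %d, features [%s]\n", x$n_trees,
              x$mtry, paste(x$features, collapse = ", ")))
  cat(sprintf("  final OOB error: %.3f\n", x$oob_error[x$n_trees]))
  cat("  importance:", paste(sprintf("%s=%.2f", names(x$importance),
                                     x$importance), collapse = ", "), "\n")
  invisible(x)
}

#' Classify waveforms with a trained forest
#'
#' Scores are tree-vote fractions per class (summing to 1); the predicted
#' class is the argmax, with ties broken deterministically in favour of the
#' first class in the model's class order.
#'
#' @param object A `wave_forest`.
#' @param newdata A `feature_table` containing the model's feature columns.
#' @param ... Unused.
#' @return An object of class `prediction_set`: list with `predicted`
#'   (character), `scores` (matrix, one column per class), `truth` (labels
#'   if present in `newdata`), `recording_id` (if present).
#' @export
predict.wave_forest <- function(object, newdata, ...) {
  missing_f <- setdiff(object$features, names(newdata))
  if (length(missing_f))
    stop("missing feature column(s): ", paste(missing_f, collapse = ", "))
  x <- as.data.frame(newdata)[, object$features, drop = FALSE]
  votes <- predict(object$rf, x, type = "vote", norm.votes = TRUE)
  votes <- votes[, object$classes, drop = FALSE]
  pred <- object$classes[max.col(votes, ties.method = "first")]
  structure(list(predicted = pred, scores = votes,
                 truth = if ("label" %in% names(newdata))
                   as.character(newdata$label) else NULL,
                 recording_id = if ("recording_id" %in% names(newdata))
                   as.character(newdata$recording_id) else NULL,
                 classes = object$classes),
            class = "prediction_set")
}

#' Sequential feature removal guided by OOB importance
#'
#' Step 1 removes every feature whose standardized OOB permutation
#' importance falls below `importance_threshold` and retrains. Subsequent
#' steps drop the single least-important remaining feature, retrain, and
#' compare held-out accuracy with the previously accepted model; reduction
#' stops when accuracy falls by more than `stop_margin` percentage points
#' or when only two features remain.
#'
#' @param train,validation Feature tables from [stratified_split()].
#' @param importance_threshold Step-1 removal threshold (default 1.0).
#' @param stop_margin Accuracy-drop stop rule in percentage points
#'   (default 5).
#' @param n_trees,seed Forwarded to [train_forest()].
#' @return List with `report` (one row per step: features kept, final OOB
#'   error, validation accuracy in %, accepted flag) and `model` (the last
#'   accepted `wave_forest`).
#' @export
reduce_model <- function(train, validation, importance_threshold = 1.0,
                         stop_margin = 5, n_trees = 50, seed = NULL) {
  val_acc <- function(model) {
    p <- predict(model, validation)
    100 * mean(p$predicted == as.character(validation$label))
  }
  feats <- feature_cols(train)
  model <- train_forest(train, n_trees = n_trees, seed = seed,
                        features = feats)
  report <- data.frame(step = 0L, n_features = length(feats),
                       features = paste(feats, collapse = "+"),
                       removed = "", oob_error = model$oob_error[n_trees],
                       val_accuracy = val_acc(model), accepted = TRUE,
                       stringsAsFactors = FALSE)
  best <- model; best_acc <- report$val_accuracy[1]
  step <- 1L
  # step 1: drop everything under the importance threshold (keep >= 2)
  low <- names(sort(model$importance[model$importance <
                                       importance_threshold]))
  while (length(feats) - length(low) < 2L && length(low))
    low <- low[-length(low)]  # keep the strongest of the sub-threshold set
  repeat {
    if (step == 1L && !length(low)) { step <- 2L; next }  # no-op step 1
    drop <- if (step == 1L) low else
      names(which.min(model$importance))
    if (length(feats) - length(drop) < 2L) break
    feats <- setdiff(feats, drop)
    model <- train_forest(train, n_trees = n_trees,
                          seed = if (is.null(seed)) NULL else seed + step,
                          features = feats)
    acc <- val_acc(model)
    accepted <- (best_acc - acc) <= stop_margin
    report <- rbind(report, data.frame(
      step = step, n_features = length(feats),
      features = paste(feats, collapse = "+"),
      removed = paste(drop, collapse = "+"),
      oob_error = model$oob_error[n_trees], val_accuracy = acc,
      accepted = accepted, stringsAsFactors = FALSE))
    if (!accepted) break
    best <- model; best_acc <- acc
    if (length(feats) <= 2L) break
    step <- step + 1L
  }
  list(report = report, model = best)
}

#' Aggregate per-waveform predictions to a recording-level call
#'
#' Each recording is assigned the modal per-waveform predicted class; ties
#' are broken by the higher mean vote-fraction score among the tied
#' classes (then by class order, deterministically).
#'
#' @param predictions A `prediction_set` whose rows carry recording IDs.
#' @return data.frame with `recording_id`, `predicted` and `n_waveforms`.
#' @export
aggregate_recording <- function(predictions) {
  stopifnot(inherits(predictions, "prediction_set"))
  rid <- predictions$recording_id
  if (is.null(rid) || !length(rid))
    stop("predictions carry no recording IDs")
  out <- lapply(unique(rid), function(r) {
    sel <- rid == r
    if (!any(sel)) stop("empty recording: ", r)
    votes <- table(factor(predictions$predicted[sel],
                          levels = predictions$classes))
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      ms <- colMeans(predictions$scores[sel, top, drop = FALSE])
      top <- top[order(-ms, match(top, predictions$classes))][1L]
    }
    data.frame(recording_id = r, predicted = top, n_waveforms = sum(sel),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Serialize / restore a trained forest
#'
#' The model is written as a single versioned RDS file.
#'
#' @param model A `wave_forest`.
#' @param path File path.
#' @return `write_forest` returns `path` invisibly; `read_forest` returns
#'   the `wave_forest`.
#' @export
write_forest <- function(model, path) {
  stopifnot(inherits(model, "wave_forest"))
  saveRDS(list(format = "cardiowave_forest", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname write_forest
#' @export
read_forest <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "cardiowave_forest"))
    stop("not a cardiowave forest file")
  obj$model
}
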