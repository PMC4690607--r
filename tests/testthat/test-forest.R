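make_table <- function(n_per_class, classes = c("a", "b", "c"),
                       seed = 1, shift = 2) {
  set.seed(seed)
  parts <- lapply(seq_along(classes), function(i) {
    n <- n_per_class[i]
    data.frame(h_max = rnorm(n, shift * i), m_up = rnorm(n, shift * i),
               m_down = rnorm(n), w = rnorm(n), h_plateau = rnorm(n),
               label = classes[i],
               recording_id = paste0(classes[i], "_r", rep(1:2, len = n)),
               membrane_id = "m1", beat_time_s = seq_len(n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  class(out) <- c("feature_table", "data.frame")
  out
}

test_that("stratified split applies the rounding rule and stays disjoint", {
  tab <- make_table(c(145, 100, 212),
                    classes = c("control", "propranolol", "isoproterenol"))
  sp <- stratified_split(tab, fraction = 0.33, seed = 4)
  tr <- table(sp$train$label)
  expect_equal(as.vector(tr[c("control", "propranolol", "isoproterenol")]),
               round(0.33 * c(145, 100, 212)))  # 48 / 33 / 70
  expect_equal(nrow(sp$train) + nrow(sp$validation), 457L)
  key <- function(d) paste(d$label, d$recording_id, d$beat_time_s)
  expect_length(intersect(key(sp$train), key(sp$validation)), 0)

  # explicit per-class counts reproduce the printed training sizes
  sp2 <- stratified_split(tab, counts = c(control = 45, propranolol = 34,
                                          isoproterenol = 70), seed = 5)
  va <- table(sp2$validation$label)
  expect_equal(as.vector(va[c("control", "propranolol", "isoproterenol")]),
               c(100, 66, 142))
  expect_equal(nrow(sp2$validation), 308L)

  # even two-class split
  tab2 <- make_table(c(10, 10), classes = c("a", "b"))
  sp3 <- stratified_split(tab2, fraction = 0.5, seed = 6)
  expect_equal(as.vector(table(sp3$train$label)), c(5L, 5L))
})

test_that("separable data trains to near-zero OOB error with the right importance", {
  tab <- make_table(c(60, 60), classes = c("a", "b"), shift = 8)
  tab$m_up <- rnorm(nrow(tab))  # only h_max separates
  m <- train_forest(tab, n_trees = 50, seed = 7)
  expect_lt(m$oob_error[50], 0.05)
  expect_equal(names(which.max(m$importance)), "h_max")
  expect_length(m$oob_error, 50)
  expect_true(all(m$oob_error >= 0 & m$oob_error <= 1))
})

test_that("training is reproducible given the seed", {
  tab <- make_table(c(40, 40, 40))
  m1 <- train_forest(tab, n_trees = 30, seed = 11)
  m2 <- train_forest(tab, n_trees = 30, seed = 11)
  expect_identical(m1$oob_error, m2$oob_error)
  expect_identical(m1$importance, m2$importance)
  p1 <- predict(m1, tab); p2 <- predict(m2, tab)
  expect_identical(p1$scores, p2$scores)
})

test_that("label permutation leaves no class information to exploit", {
  # exchangeable rows (no residual feature clustering), labels shuffled:
  # accuracy must not exceed the majority-class rate, and sits at the
  # vote-mechanism's chance level (hard votes from ~18 OOB trees per row
  # land below the always-majority rate; see the methods vignette)
  tab <- make_table(c(145, 100, 212), shift = 0, seed = 21)
  set.seed(22)
  tab$label <- sample(tab$label)
  m <- train_forest(tab, n_trees = 50, seed = 23)
  oob_acc <- 100 * (1 - m$oob_error[50])
  expect_lt(oob_acc, 100 * 212 / 457 + 5)
  expect_gt(oob_acc, 30)
  expect_true(all(m$importance < 1))  # nothing looks informative
})

test_that("prediction scores normalize and memorize pure-separation rows", {
  tab <- make_table(c(50, 50), classes = c("a", "b"), shift = 10)
  m <- train_forest(tab, n_trees = 50, seed = 9)
  p <- predict(m, tab)
  expect_equal(unname(rowSums(p$scores)), rep(1, nrow(tab)))
  expect_equal(p$predicted, tab$label)
  expect_gt(min(p$scores[cbind(seq_len(nrow(tab)),
                               match(tab$label, m$classes))]), 0.95)
  expect_error(predict(m, tab[, c("h_max", "label")]),
               "missing feature")
})

test_that("model reduction removes noise features and keeps accuracy", {
  set.seed(31)
  tab <- make_table(c(120, 120, 120), shift = 4, seed = 31)
  # h_max, m_up informative (class-shifted); the rest pure noise
  sp <- stratified_split(tab, 0.5, seed = 32)
  red <- reduce_model(sp$train, sp$validation, importance_threshold = 1,
                      n_trees = 50, seed = 33)
  step1 <- red$report[red$report$step == 1, ]
  expect_true(nrow(step1) == 1)
  removed <- strsplit(step1$removed, "+", fixed = TRUE)[[1]]
  expect_true(all(removed %in% c("m_down", "w", "h_plateau")))
  full_acc <- red$report$val_accuracy[red$report$step == 0]
  expect_lt(abs(step1$val_accuracy - full_acc), 5 + 1e-9)
  expect_true(all(c("h_max", "m_up") %in% red$model$features))
})

test_that("reduction is a no-op when all features clear the threshold", {
  tab <- make_table(c(80, 80), classes = c("a", "b"), shift = 6, seed = 41)
  for (v in c("m_up", "m_down", "w", "h_plateau"))
    tab[[v]] <- tab$h_max + rnorm(nrow(tab), 0, 0.3)
  sp <- stratified_split(tab, 0.5, seed = 42)
  red <- reduce_model(sp$train, sp$validation, importance_threshold = -Inf,
                      n_trees = 30, seed = 43)
  expect_false(any(red$report$step == 1))
})

test_that("recording aggregation takes the mode with score tie-breaks", {
  classes <- c("a", "b", "c")
  mk <- function(pred, scores, rid) structure(
    list(predicted = pred, scores = scores, recording_id = rid,
         classes = classes), class = "prediction_set")
  sc <- matrix(1 / 3, 4, 3, dimnames = list(NULL, classes))
  unan <- mk(rep("b", 4), sc, rep("r1", 4))
  expect_equal(aggregate_recording(unan)$predicted, "b")

  # 2-2 vote tie: the class with the higher mean score (0.48 vs 0.42) wins
  sc2 <- rbind(c(0.60, 0.30, 0.10), c(0.60, 0.30, 0.10),
               c(0.36, 0.54, 0.10), c(0.36, 0.54, 0.10))
  colnames(sc2) <- classes
  tie <- mk(c("a", "a", "b", "b"), sc2, rep("r1", 4))
  expect_equal(aggregate_recording(tie)$predicted, "a")
})

test_that("aggregation over many recordings is almost always right at p=0.6", {
  set.seed(51)
  classes <- c("a", "b", "c")
  n_rec <- 300; n_wf <- 60
  ok <- logical(n_rec)
  for (r in seq_len(n_rec)) {
    true_cl <- classes[(r - 1) %% 3 + 1]
    p <- ifelse(classes == true_cl, 0.6, 0.2)
    lab <- sample(classes, n_wf, replace = TRUE, prob = p)
    scores <- diag(3)[match(lab, classes), ]
    colnames(scores) <- classes
    ps <- structure(list(predicted = lab, scores = scores,
                         recording_id = rep("r", n_wf), classes = classes),
                    class = "prediction_set")
    ok[r] <- aggregate_recording(ps)$predicted == true_cl
  }
  expect_gte(100 * mean(ok), 99.5)
})

test_that("OOB error at 50 trees matches held-out error on synthetic data", {
  out <- default_regime_eval(seed = 301)
  oob_acc <- 100 * (1 - out$model$oob_error[50])
  expect_lt(abs(oob_acc - out$accuracy), 8)
})

test_that("forests serialize and restore", {
  tab <- make_table(c(30, 30), classes = c("a", "b"))
  m <- train_forest(tab, n_trees = 20, seed = 61)
  path <- file.path(tempdir(), "model.rds")
  write_forest(m, path)
  back <- read_forest(path)
  expect_identical(back$importance, m$importance)
  expect_identical(predict(back, tab)$scores, predict(m, tab)$scores)
  unlink(path)
})
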