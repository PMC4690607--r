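test_that("confusion matrices count what a hand count counts", {
  truth <- c("a", "a", "a", "a", "b", "b", "b", "c", "c", "c")
  pred  <- c("a", "a", "b", "c", "b", "b", "a", "c", "c", "a")
  cr <- confusion_report(pred, truth)
  expect_equal(as.vector(cr$confusion["a", ]), c(2, 1, 1))
  expect_equal(as.vector(cr$confusion["b", ]), c(1, 2, 0))
  expect_equal(as.vector(cr$confusion["c", ]), c(1, 0, 2))
  expect_equal(cr$overall_accuracy, 60)
  expect_equal(unname(cr$per_class_accuracy),
               c(50, 200 / 3, 200 / 3), tolerance = 1e-9)
  expect_equal(sum(cr$confusion), length(truth))

  perfect <- confusion_report(truth, truth)
  expect_equal(perfect$overall_accuracy, 100)
  expect_true(all(perfect$confusion[upper.tri(perfect$confusion)] == 0))

  expect_error(confusion_report(c("x", "y"), c("a", "b")),
               "do not overlap")
})

test_that("ROC/AUC handles perfect, inverted and chance-level scores", {
  truth <- rep(c("pos", "neg"), each = 50)
  s_perf <- c(runif(50, 0.6, 1), runif(50, 0, 0.4))
  expect_equal(roc_auc(s_perf, truth, "pos")$auc, 1.0)
  expect_equal(roc_auc(1 - s_perf, truth, "pos")$auc, 0.0)

  set.seed(99)
  n <- 10000
  truth_big <- sample(c("pos", "neg"), n, replace = TRUE)
  s_rand <- runif(n)
  expect_equal(roc_auc(s_rand, truth_big, "pos")$auc, 0.5,
               tolerance = 0.04)
})

test_that("AUC is invariant to monotone score transforms and matches pROC", {
  set.seed(17)
  truth <- sample(c("pos", "neg"), 300, replace = TRUE)
  s <- pmin(pmax(rnorm(300, ifelse(truth == "pos", 0.6, 0.4), 0.2), 0), 1)
  a1 <- roc_auc(s, truth, "pos")$auc
  a2 <- roc_auc(s^3, truth, "pos")$auc
  expect_equal(a1, a2, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(truth == "pos", s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(a1, ref, tolerance = 1e-9)
})

test_that("group statistics reproduce closed-form t and null behaviour", {
  tab <- data.frame(h_max = c(1, 2, 3, 4, 5, 6),
                    label = rep(c("g1", "g2"), each = 3))
  gs <- group_stats(tab, values = "h_max")
  expect_equal(gs$t_tests$statistic, -3.674, tolerance = 1e-3)
  expect_equal(gs$t_tests$p_value, 0.0214, tolerance = 1e-2)
  expect_equal(gs$t_tests$df, 4)

  # identical groups: t = 0, p = 1; F = 0, no Tukey pair significant
  tab2 <- data.frame(h_max = rep(c(1, 2, 3), 3),
                     label = rep(c("g1", "g2", "g3"), each = 3))
  gs2 <- group_stats(tab2, values = "h_max")
  expect_true(all(abs(gs2$t_tests$statistic) < 1e-12))
  expect_true(all(gs2$t_tests$p_value > 0.999))
  expect_equal(gs2$anova$F, 0, tolerance = 1e-12)
  expect_false(any(gs2$tukey$significant))
})

test_that("pooled t-test holds its nominal type-I error under the null", {
  # vectorized pooled-variance t over many null replicates, checked
  # against stats::t.test on a spot sample
  set.seed(7)
  n <- 10; reps <- 10000
  a <- matrix(rnorm(n * reps), n)
  b <- matrix(rnorm(n * reps), n)
  sp <- sqrt(((n - 1) * apply(a, 2, var) + (n - 1) * apply(b, 2, var)) /
               (2 * n - 2))
  tstat <- (colMeans(a) - colMeans(b)) / (sp * sqrt(2 / n))
  pvals <- 2 * pt(-abs(tstat), df = 2 * n - 2)
  expect_equal(mean(pvals < 0.05), 0.05, tolerance = 0.2)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.01)
  i <- 123
  ref <- t.test(a[, i], b[, i], var.equal = TRUE)
  expect_equal(tstat[i], unname(ref$statistic), tolerance = 1e-12)
})

test_that("evaluation reports are internally consistent", {
  out <- default_regime_eval(seed = 77)
  rep <- out$report
  expect_equal(sum(rep$confusion$confusion), nrow(out$split$validation))
  expect_true(all(rep$auc >= 0 & rep$auc <= 1))
  expect_true(all(abs(rowSums(rep$mean_scores) - 1) < 1e-9))
  # scores carry real class information: every AUC well above chance
  expect_true(all(rep$auc > 0.8))
  # recording-level aggregation is at least as accurate as waveforms
  expect_gte(rep$recording_accuracy, rep$confusion$overall_accuracy)
})

test_that("evaluation reports serialize to JSON and text", {
  skip_if_not_installed("jsonlite")
  out <- default_regime_eval(seed = 77)
  base <- file.path(tempdir(), "report")
  write_eval_report(out$report, base)
  back <- jsonlite::read_json(paste0(base, ".json"))
  expect_equal(back$overall_accuracy, out$report$confusion$overall_accuracy,
               tolerance = 1e-9)
  expect_true(file.exists(paste0(base, ".txt")))
  unlink(paste0(base, c(".json", ".txt")))
})
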