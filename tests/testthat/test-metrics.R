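# Confusion matrices, macro metrics, PR curves, replicate aggregation.

worked_cm <- function() as_cm(matrix(c(2, 0, 1, 3), 2, 2))
as_cm <- function(m) structure(m, class = c("confusion_matrix", "matrix", "array"))

test_that("confusion counts match direct enumeration", {
  cm <- confusion_matrix(c(0, 0, 1), c(0, 1, 1), k = 2)
  expect_identical(unclass(cm)[], matrix(c(1L, 0L, 1L, 1L), 2, 2))
  ident <- confusion_matrix(c(0, 1, 2, 2), c(0, 1, 2, 2), k = 3)
  expect_true(all(unclass(ident)[upper.tri(ident) | lower.tri(ident)] == 0))
  expect_error(confusion_matrix(c(0, 5), c(0, 1), k = 2), "out of range")
  expect_error(confusion_matrix(c(0, 1), c(0), k = 2), "equal length")

  set.seed(1)
  for (trial in 1:5) {
    k <- sample(2:6, 1)
    n <- sample(20:60, 1)
    yt <- sample(0:(k - 1), n, replace = TRUE)
    yp <- sample(0:(k - 1), n, replace = TRUE)
    cm <- confusion_matrix(yt, yp, k)
    brute <- matrix(0L, k, k)
    for (t in seq_len(n))
      brute[yt[t] + 1, yp[t] + 1] <- brute[yt[t] + 1, yp[t] + 1] + 1L
    expect_identical(unclass(cm)[], brute)
  }
})

test_that("the worked confusion matrix yields the hand-computed metrics", {
  cm <- worked_cm()
  expect_equal(accuracy(cm), 5 / 6, tolerance = 1e-12)
  expect_equal(macro_precision(cm), (2 / 2 + 3 / 4) / 2, tolerance = 1e-12)
  expect_equal(macro_recall(cm), (2 / 3 + 3 / 3) / 2, tolerance = 1e-12)
  expect_equal(macro_f1(cm), (4 / 5 + 6 / 7) / 2, tolerance = 1e-12)
})

test_that("perfect and degenerate matrices hit the metric boundaries", {
  perfect <- as_cm(diag(c(3, 5, 2)))
  expect_equal(accuracy(perfect), 1)
  expect_equal(macro_precision(perfect), 1)
  expect_equal(macro_recall(perfect), 1)
  expect_equal(macro_f1(perfect), 1)
  zero_diag <- as_cm(matrix(c(0, 2, 3, 0), 2, 2))
  expect_equal(accuracy(zero_diag), 0)
  # class never predicted contributes 0 to macro precision
  never_pred <- as_cm(matrix(c(3, 2, 0, 0), 2, 2))
  expect_equal(macro_precision(never_pred), (3 / 5 + 0) / 2)
  expect_error(accuracy(as_cm(matrix(0, 2, 2))), "no samples")
})

test_that("macro metrics agree with a per-class brute-force oracle", {
  set.seed(42)
  for (trial in 1:100) {
    k <- sample(2:7, 1)
    cm <- matrix(rpois(k * k, 3), k, k)
    o <- brute <- list(p = 0, r = 0, f = 0)
    for (i in seq_len(k)) {
      tp <- cm[i, i]
      fp <- sum(cm[, i]) - tp
      fn <- sum(cm[i, ]) - tp
      brute$p <- brute$p + (if (tp + fp > 0) tp / (tp + fp) else 0)
      brute$r <- brute$r + (if (tp + fn > 0) tp / (tp + fn) else 0)
      brute$f <- brute$f + (if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0)
    }
    expect_equal(macro_precision(as_cm(cm)), brute$p / k, tolerance = 1e-12)
    expect_equal(macro_recall(as_cm(cm)), brute$r / k, tolerance = 1e-12)
    expect_equal(macro_f1(as_cm(cm)), brute$f / k, tolerance = 1e-12)
    expect_equal(accuracy(as_cm(cm)), sum(diag(cm)) / sum(cm), tolerance = 1e-12)
  }
})

test_that("macro metrics agree with an independent reference implementation", {
  skip_if_not_installed("caret")
  set.seed(7)
  for (trial in 1:10) {
    k <- sample(3:5, 1)
    n <- 200
    yt <- factor(sample(letters[1:k], n, replace = TRUE), levels = letters[1:k])
    yp <- factor(sample(letters[1:k], n, replace = TRUE), levels = letters[1:k])
    cm <- confusion_matrix(as.integer(yt) - 1L, as.integer(yp) - 1L, k)
    ref <- caret::confusionMatrix(yp, yt)$byClass
    if (any(is.na(ref[, c("Precision", "Recall", "F1")]))) next
    expect_equal(macro_precision(cm), mean(ref[, "Precision"]), tolerance = 1e-9)
    expect_equal(macro_recall(cm), mean(ref[, "Recall"]), tolerance = 1e-9)
    expect_equal(macro_f1(cm), mean(ref[, "F1"]), tolerance = 1e-9)
  }
})

test_that("macro metrics are invariant under class permutation", {
  set.seed(3)
  cm <- matrix(rpois(25, 4), 5, 5)
  perm <- sample(5)
  cmp <- cm[perm, perm]
  expect_equal(macro_precision(as_cm(cm)), macro_precision(as_cm(cmp)), tolerance = 1e-12)
  expect_equal(macro_recall(as_cm(cm)), macro_recall(as_cm(cmp)), tolerance = 1e-12)
  expect_equal(macro_f1(as_cm(cm)), macro_f1(as_cm(cmp)), tolerance = 1e-12)
})

test_that("PR curves follow the threshold-sweep construction", {
  scores <- cbind(1 - c(0.9, 0.8, 0.3), c(0.9, 0.8, 0.3))
  pc <- pr_curve(scores, c(1, 0, 1), 1)
  expect_equal(pc$recall, c(0.5, 0.5, 1.0))
  expect_equal(pc$precision, c(1.0, 0.5, 2 / 3))
  expect_true(all(diff(pc$recall) >= 0))

  # perfectly separated scores -> area 1
  s2 <- cbind(c(0.1, 0.2, 0.8, 0.9), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(pr_auc(pr_curve(s2, c(1, 1, 0, 0), 1)), 1.0)

  # inverted scores -> area at most the positive prevalence... checked by
  # enumeration against the definition
  s3 <- cbind(c(0.9, 0.8, 0.2, 0.1), c(0.1, 0.2, 0.8, 0.9))
  expect_lte(pr_auc(pr_curve(s3, c(1, 1, 0, 0), 1)), 0.5)

  expect_error(pr_curve(s2, c(0, 0, 0, 0), 1), "no positive")
  expect_error(pr_curve(s2, c(1, 1, 0, 0), 5), "out of range")
})

test_that("report tidiers and aggregation behave", {
  rep1 <- metrics_report(c(0, 0, 1, 1), c(0, 0, 1, 0), k = 2)
  td <- tidy(rep1)
  expect_identical(nrow(td), 2L)
  expect_named(glance(rep1), c("acc", "mp", "mr", "mf", "n", "k"))
  expect_equal(tidy(rep1)$f1, c(2 * 2 / (2 * 2 + 1), 2 * 1 / (2 * 1 + 1)),
               tolerance = 1e-12)

  single <- aggregate_reports(list(rep1))
  expect_true(all(single$sd == 0))
  r2 <- rep1; r2$acc <- 0.9; rep1$acc <- 0.95
  agg <- aggregate_reports(list(rep1, r2))
  expect_equal(agg$mean[agg$metric == "acc"], 0.925, tolerance = 1e-12)
  expect_equal(agg$sd[agg$metric == "acc"], stats::sd(c(0.95, 0.9)), tolerance = 1e-12)
})

test_that("plot and export helpers produce artifacts", {
  rep1 <- metrics_report(c(0, 1, 1, 0), c(0, 1, 0, 0), k = 2,
                         class_names = c("a", "b"))
  p <- autoplot(rep1$confusion)
  expect_s3_class(p, "ggplot")
  scores <- matrix(runif(8), 4, 2)
  prs <- pr_curves(scores, c(0, 1, 1, 0), c("a", "b"))
  expect_s3_class(autoplot(prs), "ggplot")
  dir <- withr::local_tempdir()
  paths <- write_metrics(rep1, dir, scores, c(0, 1, 1, 0))
  expect_true(file.exists(file.path(dir, "metrics.json")))
  expect_true(file.exists(file.path(dir, "confusion.csv")))
  expect_true(file.exists(file.path(dir, "pr_curves.png")))
})
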