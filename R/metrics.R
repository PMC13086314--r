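# Imbalance-aware evaluation: confusion matrices, accuracy and macro
# precision/recall/F1, one-vs-rest precision-recall curves, and replicate
# aggregation as mean +/- SD.
#
# Zero-denominator convention: a class that is never predicted contributes
# precision 0, and a class with no true samples contributes recall 0, to the
# macro means. This penalises degenerate predictors on imbalanced data
# instead of silently dropping rare classes.

#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

#' Multiclass confusion matrix
#'
#' @param y_true,y_pred Integer label vectors in `[0, k)` (0-based) or
#'   factors with identical levels.
#' @param k Number of classes; inferred from factor levels if omitted.
#' @param class_names Optional character vector of class names.
#' @return A `confusion_matrix`: `k x k` integer matrix, rows = true class,
#'   columns = predicted class.
#' @export
#' @examples
#' confusion_matrix(c(0, 0, 1), c(0, 1, 1), k = 2)
confusion_matrix <- function(y_true, y_pred, k = NULL, class_names = NULL) {
  if (is.factor(y_true) || is.factor(y_pred)) {
    lev <- levels(as.factor(y_true))
    class_names <- class_names %||% lev
    y_true <- as.integer(factor(y_true, levels = lev)) - 1L
    y_pred <- as.integer(factor(y_pred, levels = lev)) - 1L
  }
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  k <- as.integer(k %||% (max(y_true, y_pred) + 1L))
  bad <- which(y_true < 0 | y_true >= k | y_pred < 0 | y_pred >= k)
  if (length(bad))
    stop("label out of range [0, ", k, ") at index ", bad[1])
  cm <- matrix(0L, k, k)
  for (t in seq_along(y_true))
    cm[y_true[t] + 1L, y_pred[t] + 1L] <- cm[y_true[t] + 1L, y_pred[t] + 1L] + 1L
  if (!is.null(class_names)) dimnames(cm) <- list(true = class_names,
                                                  predicted = class_names)
  structure(cm, class = c("confusion_matrix", "matrix", "array"))
}

as_confusion_matrix <- function(cm) {
  if (inherits(cm, "confusion_matrix")) return(cm)
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), all(cm >= 0))
  structure(cm, class = c("confusion_matrix", "matrix", "array"))
}

cm_counts <- function(cm) {
  cm <- as_confusion_matrix(cm)
  tp <- diag(cm)
  list(tp = tp, fn = rowSums(cm) - tp, fp = colSums(cm) - tp,
       n = sum(cm), k = nrow(cm))
}

#' Overall accuracy from a confusion matrix
#' @param cm A [confusion_matrix()] or square count matrix.
#' @return Accuracy in `[0, 1]` (trace over total count).
#' @export
accuracy <- function(cm) {
  c0 <- cm_counts(cm)
  if (c0$n == 0) stop("confusion matrix has no samples")
  sum(c0$tp) / c0$n
}

safe_div <- function(num, den) ifelse(den > 0, num / ifelse(den > 0, den, 1), 0)

#' Macro precision
#' @inheritParams accuracy
#' @return Mean over classes of `TP_i / (TP_i + FP_i)`; classes never
#'   predicted contribute 0.
#' @export
macro_precision <- function(cm) {
  c0 <- cm_counts(cm)
  if (c0$n == 0) stop("confusion matrix has no samples")
  mean(safe_div(c0$tp, c0$tp + c0$fp))
}

#' Macro recall
#' @inheritParams accuracy
#' @return Mean over classes of `TP_i / (TP_i + FN_i)`; classes with no true
#'   samples contribute 0.
#' @export
macro_recall <- function(cm) {
  c0 <- cm_counts(cm)
  if (c0$n == 0) stop("confusion matrix has no samples")
  mean(safe_div(c0$tp, c0$tp + c0$fn))
}

#' Macro F1
#' @inheritParams accuracy
#' @return Mean over classes of `2 TP_i / (2 TP_i + FP_i + FN_i)` (the mean
#'   of per-class F1 values, not the harmonic mean of macro precision and
#'   macro recall).
#' @export
macro_f1 <- function(cm) {
  c0 <- cm_counts(cm)
  if (c0$n == 0) stop("confusion matrix has no samples")
  mean(safe_div(2 * c0$tp, 2 * c0$tp + c0$fp + c0$fn))
}

#' Full evaluation report from predictions
#'
#' @param y_true,y_pred 0-based integer labels (or factors).
#' @param k Number of classes.
#' @param class_names Optional class names.
#' @return A `metrics_report`: overall accuracy and macro
#'   precision/recall/F1, the confusion matrix, and a per-class tibble.
#' @export
metrics_report <- function(y_true, y_pred, k = NULL, class_names = NULL) {
  cm <- confusion_matrix(y_true, y_pred, k, class_names)
  report_from_cm(cm)
}

report_from_cm <- function(cm) {
  cm <- as_confusion_matrix(cm)
  c0 <- cm_counts(cm)
  per_class <- tibble(
    class = dimnames(cm)[[1]] %||% as.character(seq_len(c0$k) - 1L),
    support = c0$tp + c0$fn,
    precision = safe_div(c0$tp, c0$tp + c0$fp),
    recall = safe_div(c0$tp, c0$tp + c0$fn),
    f1 = safe_div(2 * c0$tp, 2 * c0$tp + c0$fp + c0$fn))
  structure(list(acc = accuracy(cm), mp = macro_precision(cm),
                 mr = macro_recall(cm), mf = macro_f1(cm),
                 per_class = per_class, confusion = cm,
                 convention = "zero-denominator classes contribute 0"),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Acc %.4f | MP %.4f | MR %.4f | MF %.4f  (n = %d, k = %d)\n",
              x$acc, x$mp, x$mr, x$mf, sum(x$confusion), nrow(x$confusion)))
  invisible(x)
}

#' Tidy a metrics report into per-class rows
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return Tibble with one row per class: support, precision, recall, F1.
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' One-row summary of a metrics report
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return Tibble with columns `acc`, `mp`, `mr`, `mf`, `n`, `k`.
#' @export
glance.metrics_report <- function(x, ...) {
  tibble(acc = x$acc, mp = x$mp, mr = x$mr, mf = x$mf,
         n = sum(x$confusion), k = nrow(x$confusion))
}

#' Tidy a confusion matrix
#' @param x A `confusion_matrix`.
#' @param normalize Divide counts by row sums (true-class totals).
#' @param ... Unused.
#' @return Tibble with columns `true`, `predicted`, `count` (and `prop`).
#' @export
tidy.confusion_matrix <- function(x, normalize = FALSE, ...) {
  k <- nrow(x)
  nm <- dimnames(x)[[1]] %||% as.character(seq_len(k) - 1L)
  out <- tibble(true = rep(nm, times = k),
                predicted = rep(nm, each = k),
                count = as.vector(unclass(x)))
  if (normalize) {
    rs <- rowSums(x)[match(out$true, nm)]
    out$prop <- ifelse(rs > 0, out$count / rs, 0)
  }
  out
}

#' Plot a normalised confusion-matrix heatmap
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy.confusion_matrix(object, normalize = TRUE)
  nm <- unique(df$true)
  df$true <- factor(df$true, levels = rev(nm))
  df$predicted <- factor(df$predicted, levels = nm)
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true,
                                   fill = .data$prop)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$prop)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "Predicted class", y = "True class",
                  fill = "Row-normalised") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' One-vs-rest precision-recall curve
#'
#' Sweeps every distinct score of the target class as a decision threshold
#' (samples with `score >= threshold` are predicted positive) and records
#' `(recall, precision)` at each step; recall is nondecreasing along the
#' sweep. The area is computed by the rectangle rule over recall increments.
#'
#' @param scores `(n, k)` matrix of per-sample class scores (raw scores or
#'   probabilities).
#' @param y_true 0-based integer labels of length `n`.
#' @param class_index 0-based index of the positive class.
#' @return A `pr_curve` tibble with columns `threshold`, `recall`,
#'   `precision`, and attribute `auc`.
#' @export
pr_curve <- function(scores, y_true, class_index) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1)
  if (class_index < 0 || class_index >= ncol(scores) + 0L)
    stop("class_index out of range")
  s <- scores[, class_index + 1L]
  pos <- y_true == class_index
  npos <- sum(pos)
  if (npos == 0)
    stop("class ", class_index, " has no positive samples; PR curve undefined")
  th <- sort(unique(s), decreasing = TRUE)
  rec <- prec <- numeric(length(th))
  for (i in seq_along(th)) {
    sel <- s >= th[i]
    tp <- sum(sel & pos)
    rec[i] <- tp / npos
    prec[i] <- tp / sum(sel)
  }
  auc <- sum(diff(c(0, rec)) * prec)
  structure(tibble(threshold = th, recall = rec, precision = prec),
            auc = auc, class_index = class_index,
            class = c("pr_curve", "tbl_df", "tbl", "data.frame"))
}

#' Area under a precision-recall curve
#' @param x A `pr_curve`, or arguments forwarded to [pr_curve()].
#' @param ... Forwarded to [pr_curve()] when `x` is a score matrix.
#' @return Scalar area in `[0, 1]`.
#' @export
pr_auc <- function(x, ...) {
  if (!inherits(x, "pr_curve")) x <- pr_curve(x, ...)
  attr(x, "auc")
}

#' Precision-recall curves for every class
#'
#' @param scores `(n, k)` score matrix.
#' @param y_true 0-based integer labels.
#' @param class_names Optional class names.
#' @return A tibble of PR points for all classes with at least one positive
#'   sample (classes without positives are flagged with a warning), with an
#'   `auc` tibble attribute.
#' @export
pr_curves <- function(scores, y_true, class_names = NULL) {
  k <- ncol(scores)
  nm <- class_names %||% as.character(seq_len(k) - 1L)
  out <- list(); aucs <- list()
  for (ci in seq_len(k) - 1L) {
    if (!any(y_true == ci)) {
      warning("class ", nm[ci + 1], " has no positive samples; skipped")
      next
    }
    cur <- pr_curve(scores, y_true, ci)
    out[[length(out) + 1L]] <- tibble(class = nm[ci + 1],
                                      threshold = cur$threshold,
                                      recall = cur$recall,
                                      precision = cur$precision)
    aucs[[length(aucs) + 1L]] <- tibble(class = nm[ci + 1],
                                        auc = attr(cur, "auc"))
  }
  structure(dplyr::bind_rows(out), auc = dplyr::bind_rows(aucs),
            class = c("pr_curve_set", "tbl_df", "tbl", "data.frame"))
}

#' Plot one-vs-rest precision-recall curves
#' @param object A `pr_curve_set` from [pr_curves()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pr_curve_set <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$recall, .data$precision,
                                       colour = .data$class)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision", colour = "Class") +
    ggplot2::theme_minimal()
}

#' Aggregate replicate metric reports as mean +/- SD
#'
#' @param reports List of `metrics_report` objects (one per seed replicate).
#' @return Tibble with one row per metric: `mean`, `sd` (sample SD, `n - 1`
#'   denominator; 0 for a single replicate), and `n_replicates`.
#' @export
aggregate_reports <- function(reports) {
  stopifnot(length(reports) >= 1)
  vals <- vapply(reports, function(r) c(acc = r$acc, mp = r$mp,
                                        mr = r$mr, mf = r$mf),
                 numeric(4))
  sds <- if (length(reports) == 1) rep(0, 4) else apply(vals, 1, stats::sd)
  tibble(metric = c("acc", "mp", "mr", "mf"),
         mean = unname(rowMeans(vals)), sd = unname(sds),
         n_replicates = length(reports))
}

#' Write a metrics report (JSON) plus confusion/PR tables (CSV)
#'
#' @param report A `metrics_report`.
#' @param dir Output directory (created if missing).
#' @param scores,y_true Optional score matrix and labels to also write PR
#'   curve points and plots.
#' @return Invisibly, the paths written.
#' @export
write_metrics <- function(report, dir, scores = NULL, y_true = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  j <- file.path(dir, "metrics.json")
  jsonlite::write_json(list(acc = report$acc, mp = report$mp, mr = report$mr,
                            mf = report$mf, convention = report$convention,
                            per_class = report$per_class),
                       j, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, j)
  cmp <- file.path(dir, "confusion.csv")
  utils::write.csv(tidy.confusion_matrix(report$confusion, normalize = TRUE),
                   cmp, row.names = FALSE)
  paths <- c(paths, cmp)
  grDevices::png(file.path(dir, "confusion.png"), 900, 800, res = 120)
  print(autoplot.confusion_matrix(report$confusion))
  grDevices::dev.off()
  paths <- c(paths, file.path(dir, "confusion.png"))
  if (!is.null(scores)) {
    prs <- suppressWarnings(pr_curves(scores, y_true,
                                      dimnames(report$confusion)[[1]]))
    prp <- file.path(dir, "pr_curves.csv")
    utils::write.csv(as.data.frame(prs), prp, row.names = FALSE)
    grDevices::png(file.path(dir, "pr_curves.png"), 900, 700, res = 120)
    print(autoplot.pr_curve_set(prs))
    grDevices::dev.off()
    paths <- c(paths, prp, file.path(dir, "pr_curves.png"))
  }
  invisible(paths)
}
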