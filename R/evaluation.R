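#' Confusion matrix of a binary prediction
#'
#' Counts with tumour as the positive class.
#'
#' @param y_true,y_pred Equal-length binary vectors (any encoding accepted by
#'   the package's label mapping; factors with levels normal/tumour pass
#'   through).
#' @return A `confusion_matrix` object with integer fields `TP`, `FP`, `FN`,
#'   `TN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have the same length", call. = FALSE)
  t_pos <- as_positive(y_true)
  p_pos <- as_positive(y_pred)
  structure(list(TP = sum(t_pos & p_pos), FP = sum(!t_pos & p_pos),
                 FN = sum(t_pos & !p_pos), TN = sum(!t_pos & !p_pos)),
            class = "confusion_matrix")
}

# coerce assorted binary encodings to "is tumour/positive"
as_positive <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.logical(y)) return(y)
  if (is.numeric(y)) return(y == 1)
  tolower(y) %in% c("tumour", "tumor", "positive", "1", "true")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> TP=", x$TP, " FP=", x$FP, " FN=", x$FN,
      " TN=", x$TN, "\n", sep = "")
  invisible(x)
}

metric_or_zero <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (zero denominator); reported as 0",
            call. = FALSE)
    return(0)
  }
  num / den
}

#' Classification metrics from a confusion matrix
#'
#' `accuracy = (TP + TN) / (TP + FN + FP + TN)`, `recall = TP / (TP + FN)`,
#' `precision = TP / (TP + FP)`, `f1 = 2 P R / (P + R)`. Degenerate
#' denominators yield 0 with a warning rather than NaN so report tables stay
#' complete.
#'
#' @param cm A [confusion()] result.
#' @return A number in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  metric_or_zero(cm$TP + cm$TN, cm$TP + cm$FN + cm$FP + cm$TN, "accuracy")
}

#' @rdname accuracy
#' @export
recall <- function(cm) metric_or_zero(cm$TP, cm$TP + cm$FN, "recall")

#' @rdname accuracy
#' @export
precision <- function(cm) metric_or_zero(cm$TP, cm$TP + cm$FP, "precision")

#' @rdname accuracy
#' @export
f1 <- function(cm) {
  p <- precision(cm); r <- recall(cm)
  metric_or_zero(2 * p * r, p + r, "F1")
}

#' Harmonic mean of a precision/recall pair
#'
#' Convenience for recomputing an F-measure directly from reported precision
#' and recall values.
#'
#' @param precision,recall Numbers in `[0, 1]`.
#' @return `2 P R / (P + R)`, or 0 with a warning when both are 0.
#' @export
f1_score <- function(precision, recall) {
  metric_or_zero(2 * precision * recall, precision + recall, "F1")
}

#' Area under the ROC curve
#'
#' Computed through the rank statistic (Mann-Whitney form) with ties
#' averaged: the probability that a random positive sample scores higher
#' than a random negative one.
#'
#' @param y_true Binary truth vector containing both classes.
#' @param scores Real-valued scores, higher = more tumour-like.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores))
    stop("y_true and scores must have the same length", call. = FALSE)
  pos <- as_positive(y_true)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("roc_auc requires both classes in y_true", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentage reduction in gene count
#'
#' `100 * (1 - n_after / n_before)`, reported to one decimal place — the
#' bookkeeping used when quoting how much of a dataset a selection stage
#' removed.
#'
#' @param n_before,n_after Gene counts before and after selection, with
#'   `n_before >= n_after >= 0` and `n_before > 0`.
#' @return Percentage, rounded to 1 dp.
#' @export
reduction_percentage <- function(n_before, n_after) {
  if (n_before <= 0 || n_after < 0 || n_after > n_before)
    stop("need n_before >= n_after >= 0 and n_before > 0", call. = FALSE)
  round(100 * (1 - n_after / n_before), 1)
}

#' Evaluate classifiers on a selected gene subset
#'
#' Trains each requested classifier on the subset and reports precision,
#' recall, F-measure, ROC area and accuracy, one row per classifier.
#' Holdout plans evaluate the held-out partition; k-fold plans pool the
#' out-of-fold predictions into a single confusion matrix (declared in the
#' report) rather than averaging per-fold metrics.
#'
#' @param ds An `expression_dataset`.
#' @param subset A [feature_subset()], integer gene indices, or character
#'   gene identifiers.
#' @param classifiers Character vector of classifier names and/or
#'   [classifier_spec()] objects.
#' @param plan A [split_plan()].
#' @param seed Integer seed for the classifier engines.
#' @return An `evaluation_report`: `metrics` (data.frame with one row per
#'   classifier), `confusions` (named list), `protocol`, `pooling`,
#'   `subset`, `seed`.
#' @export
evaluate_classifiers <- function(ds, subset,
                                 classifiers = c("svm", "nb", "dt", "rf",
                                                 "knn", "mlp"),
                                 plan = split_plan("holdout",
                                                   train_fraction = 0.7),
                                 seed = 0L) {
  assert_dataset(ds)
  idx <- resolve_subset(ds, subset)
  if (!length(idx)) stop("subset selects no genes", call. = FALSE)
  if (!is.list(classifiers)) classifiers <- as.list(classifiers)
  specs <- lapply(classifiers, as_classifier)
  names(specs) <- vapply(specs, `[[`, "", "name")

  x <- ds$matrix[, idx, drop = FALSE]
  y <- ds$labels
  folds <- if (plan$kind == "kfold") make_split(y, plan) else
    list(make_split(y, plan)$test)

  rows <- list(); cms <- list()
  for (nm in names(specs)) {
    truth <- factor(character(0), levels = levels(y))
    pred <- truth; score <- numeric(0)
    for (test in folds) {
      train <- setdiff(seq_along(y), test)
      out <- fit_predict(specs[[nm]], x[train, , drop = FALSE], y[train],
                         x[test, , drop = FALSE],
                         seed = derive_seed(seed, nm))
      truth <- c(truth, y[test]); pred <- c(pred, out$class)
      score <- c(score, out$score)
    }
    cm <- confusion(truth, pred)
    cms[[nm]] <- cm
    rows[[nm]] <- data.frame(
      classifier = nm,
      precision = precision(cm), recall = recall(cm), f_measure = f1(cm),
      roc_area = roc_auc(truth, score), accuracy = accuracy(cm))
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  structure(list(metrics = metrics, confusions = cms, protocol = plan,
                 pooling = if (plan$kind == "kfold") "pooled out-of-fold"
                           else "holdout test partition",
                 subset = ds$gene_ids[idx], seed = as.integer(seed)),
            class = "evaluation_report")
}

resolve_subset <- function(ds, subset) {
  if (inherits(subset, "feature_subset")) return(subset$indices)
  if (is.character(subset)) {
    idx <- match(subset, ds$gene_ids)
    if (anyNA(idx))
      stop("unknown gene identifiers in subset: ",
           paste(utils::head(subset[is.na(idx)], 5), collapse = ", "),
           call. = FALSE)
    return(idx)
  }
  as.integer(subset)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", length(x$subset), " genes, ",
      x$pooling, "\n", sep = "")
  m <- x$metrics
  m$accuracy <- sprintf("%.1f%%", 100 * m$accuracy)
  for (col in c("precision", "recall", "f_measure", "roc_area"))
    m[[col]] <- sprintf("%.3f", m[[col]])
  print(m, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report to TSV and JSON
#'
#' The TSV mirrors the conventional benchmark layout (Classifier, Precision,
#' Recall, F-Measure, ROC Area, Accuracy%); the JSON carries the full
#' confusion matrices alongside the metric rows.
#'
#' @param report An [evaluate_classifiers()] result.
#' @param tsv,json Output paths (either may be `NULL` to skip).
#' @return Invisibly, the report.
#' @export
write_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) {
    m <- report$metrics
    out <- data.frame(Classifier = toupper(m$classifier),
                      Precision = round(m$precision, 3),
                      Recall = round(m$recall, 3),
                      `F-Measure` = round(m$f_measure, 3),
                      `ROC Area` = round(m$roc_area, 3),
                      Accuracy = sprintf("%.1f%%", 100 * m$accuracy),
                      check.names = FALSE)
    utils::write.table(out, tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(metrics = report$metrics,
           confusions = lapply(report$confusions, unclass),
           pooling = report$pooling, subset = report$subset,
           seed = report$seed),
      json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
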