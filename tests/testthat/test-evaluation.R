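test_that("confusion counts follow the tumour-positive convention", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unclass(cm)[c("TP", "FP", "FN", "TN")],
               list(TP = 2L, FP = 0L, FN = 0L, TN = 2L))
  cm2 <- confusion(c(1, 0, 0), c(1, 1, 1))
  expect_equal(unclass(cm2)[c("TP", "FP", "FN", "TN")],
               list(TP = 1L, FP = 2L, FN = 0L, TN = 0L))
  cm3 <- confusion(c(1, 1, 1, 0, 0), c(1, 0, 1, 1, 0))
  expect_equal(unclass(cm3)[c("TP", "FP", "FN", "TN")],
               list(TP = 2L, FP = 1L, FN = 1L, TN = 1L))
  expect_error(confusion(1:3, 1:4), "length")
  # factor labels work identically
  f <- factor(c("tumour", "normal"), levels = c("normal", "tumour"))
  expect_equal(confusion(f, f)$TP, 1L)
})

test_that("metrics implement their defining ratios", {
  cm <- list(TP = 1L, FP = 1L, FN = 1L, TN = 1L)
  class(cm) <- "confusion_matrix"
  expect_equal(accuracy(cm), 0.5)
  expect_equal(precision(cm), 0.5)
  expect_equal(recall(cm), 0.5)
  expect_equal(f1(cm), 0.5)

  # degenerate denominators warn and return 0
  cm0 <- structure(list(TP = 0L, FP = 0L, FN = 0L, TN = 4L),
                   class = "confusion_matrix")
  expect_warning(p <- precision(cm0), "undefined")
  expect_equal(p, 0)

  # property: bounds, F1 between P and R, accuracy identity
  set.seed(3)
  for (i in 1:25) {
    cm <- structure(as.list(setNames(rpois(4, 5) + c(1, 0, 0, 1),
                                     c("TP", "FP", "FN", "TN"))),
                    class = "confusion_matrix")
    total <- cm$TP + cm$FP + cm$FN + cm$TN
    expect_equal(accuracy(cm) * total, cm$TP + cm$TN, tolerance = 1e-12)
    vals <- c(accuracy(cm), precision(cm), recall(cm), f1(cm))
    expect_true(all(vals >= 0 & vals <= 1))
    expect_gte(f1(cm), min(precision(cm), recall(cm)) - 1e-12)
    expect_lte(f1(cm), max(precision(cm), recall(cm)) + 1e-12)
  }
})

test_that("F-measure recomputed from precision/recall matches reports", {
  expect_equal(round(f1_score(0.80, 1), 2), 0.89)
  expect_equal(round(f1_score(0.947, 1), 3), 0.973)
  expect_equal(round(f1_score(0.95, 0.95), 2), 0.95)
})

test_that("rank-statistic AUC matches pair enumeration and reverses cleanly", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1)), 0.75)
  set.seed(5)
  y <- rep(c(1, 0), 500)
  s <- runif(1000)
  expect_lt(abs(roc_auc(y, s) - 0.5), 0.06)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")

  for (i in 1:10) {
    set.seed(i)
    y <- sample(c(0, 1), 20, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(y)) < 2) next
    s <- rnorm(20)
    expect_equal(roc_auc(y, s), oracle_auc(y, s), tolerance = 1e-12)
    expect_equal(roc_auc(y, s) + roc_auc(y, -s), 1, tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  y <- sample(c(0, 1), 40, replace = TRUE)
  s <- rnorm(40) + y
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(y, s), ref, tolerance = 1e-9)
})

test_that("reduction percentages reproduce the selection bookkeeping", {
  expect_equal(reduction_percentage(2000, 68), 96.6)
  expect_equal(reduction_percentage(7457, 35), 99.5)
  expect_equal(reduction_percentage(500, 500), 0)
  expect_error(reduction_percentage(10, 20), "n_before")
  expect_error(reduction_percentage(0, 0), "n_before")
})

test_that("the evaluation harness reports every requested classifier", {
  ds <- make_separable(n = 40, n_noise = 4, seed = 3)
  rep_ <- evaluate_classifiers(ds, 1L, classifiers = c("knn", "nb", "dt"),
                               plan = split_plan("holdout",
                                                 train_fraction = 0.7,
                                                 seed = 1))
  expect_equal(nrow(rep_$metrics), 3)
  expect_equal(rep_$metrics$classifier, c("knn", "nb", "dt"))
  # a perfectly separating gene is classified perfectly
  expect_true(all(rep_$metrics$accuracy == 1))
  expect_true(all(rep_$metrics$f_measure == 1))
  expect_error(evaluate_classifiers(ds, 1L, classifiers = "boost"),
               "svm")
})

test_that("k-fold evaluation pools out-of-fold predictions over all samples", {
  ds <- make_separable(n = 30, n_noise = 3, seed = 6)
  rep_ <- evaluate_classifiers(ds, c(1L, 2L), classifiers = "knn",
                               plan = split_plan("kfold", k = 5, seed = 2))
  cm <- rep_$confusions$knn
  expect_equal(cm$TP + cm$FP + cm$FN + cm$TN, 30)
  expect_match(rep_$pooling, "pooled")
})

test_that("planted genes outperform a random subset of the same size", {
  out <- generate_expression(synthetic_spec(150, 60, n_informative = 5,
                                            effect_size = 2, seed = 0))
  ds <- out$dataset
  plan <- split_plan("holdout", train_fraction = 0.7, seed = 0)
  planted <- evaluate_classifiers(ds, out$truth$informative_indices,
                                  classifiers = "knn", plan = plan)
  set.seed(1)
  rand_idx <- sample(setdiff(seq_len(60), out$truth$informative_indices), 5)
  random <- evaluate_classifiers(ds, rand_idx, classifiers = "knn",
                                 plan = plan)
  expect_gte(planted$metrics$accuracy, random$metrics$accuracy)
})

test_that("reports serialize to the tabular layout", {
  ds <- make_separable(n = 30, n_noise = 3, seed = 7)
  rep_ <- evaluate_classifiers(ds, 1L, classifiers = "knn",
                               plan = split_plan("holdout", seed = 3))
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "report.tsv")
  write_report(rep_, tsv = tsv, json = file.path(dir, "report.json"))
  tab <- read.delim(tsv, check.names = FALSE)
  expect_equal(colnames(tab),
               c("Classifier", "Precision", "Recall", "F-Measure",
                 "ROC Area", "Accuracy"))
  expect_match(tab$Accuracy[1], "%$")
})
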