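#' Describe a classifier
#'
#' Thin declarative wrapper over the fitting engines used throughout the
#' package: support vector machine (`svm`, e1071), naive Bayes (`nb`,
#' e1071), decision tree (`dt`, rpart), random forest (`rf`, randomForest),
#' k-nearest neighbours (`knn`, class) and a multilayer perceptron (`mlp`,
#' nnet) standing in for a deep network. Hyperparameters default to the
#' library defaults and can be overridden through `...`.
#'
#' @param name One of `"svm"`, `"nb"`, `"dt"`, `"rf"`, `"knn"`, `"mlp"`.
#' @param ... Named hyperparameter overrides (e.g. `k = 3` for knn,
#'   `size = 16` for mlp).
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(name, ...) {
  supported <- c("svm", "nb", "dt", "rf", "knn", "mlp")
  if (!name %in% supported)
    stop("unknown classifier '", name, "'; supported: ",
         paste(supported, collapse = ", "), call. = FALSE)
  structure(list(name = name, params = list(...)), class = "classifier_spec")
}

as_classifier <- function(x) {
  if (inherits(x, "classifier_spec")) x else classifier_spec(x)
}

# Train on (xtr, ytr), predict classes and tumour-probability scores on xte.
# Engines that consume randomness run under a fixed internal seed so that
# fitness evaluations are reproducible.
fit_predict <- function(spec, xtr, ytr, xte, seed = 1L) {
  spec <- as_classifier(spec)
  p <- spec$params
  ytr <- factor(ytr, levels = c("normal", "tumour"))
  lev <- levels(ytr)
  with_seed(derive_seed(seed, paste0("clf-", spec$name)), {
    switch(spec$name,
      knn = {
        k <- p$k %||% 1L
        pred <- class::knn(xtr, xte, ytr, k = k, prob = TRUE)
        win <- attr(pred, "prob")
        score <- ifelse(pred == "tumour", win, 1 - win)
        list(class = factor(pred, levels = lev), score = score)
      },
      svm = {
        fit <- e1071::svm(xtr, ytr, probability = TRUE, scale = FALSE,
                          kernel = p$kernel %||% "radial",
                          cost = p$cost %||% 1)
        pr <- predict(fit, xte, probability = TRUE)
        score <- attr(pr, "probabilities")[, "tumour"]
        list(class = factor(pr, levels = lev), score = as.numeric(score))
      },
      nb = {
        fit <- e1071::naiveBayes(as.data.frame(xtr), ytr)
        raw <- predict(fit, as.data.frame(xte), type = "raw")
        score <- raw[, "tumour"]
        cls <- factor(ifelse(score >= 0.5, "tumour", "normal"), levels = lev)
        list(class = cls, score = as.numeric(score))
      },
      dt = {
        df <- data.frame(.y = ytr, xtr, check.names = TRUE)
        nd <- data.frame(xte, check.names = TRUE)
        colnames(nd) <- colnames(df)[-1]
        fit <- rpart::rpart(.y ~ ., df, method = "class",
                            control = rpart::rpart.control(
                              minsplit = p$minsplit %||% 5L,
                              cp = p$cp %||% 0.01))
        score <- predict(fit, nd, type = "prob")[, "tumour"]
        cls <- factor(ifelse(score >= 0.5, "tumour", "normal"), levels = lev)
        list(class = cls, score = as.numeric(score))
      },
      rf = {
        fit <- randomForest::randomForest(xtr, ytr,
                                          ntree = p$ntree %||% 500L)
        score <- predict(fit, xte, type = "prob")[, "tumour"]
        cls <- factor(ifelse(score >= 0.5, "tumour", "normal"), levels = lev)
        list(class = cls, score = as.numeric(score))
      },
      mlp = {
        size <- p$size %||% 32L
        fit <- nnet::nnet(xtr, as.numeric(ytr == "tumour"), size = size,
                          decay = p$decay %||% 0.01,
                          maxit = p$maxit %||% 200L,
                          entropy = TRUE, trace = FALSE,
                          MaxNWts = 100000L)
        score <- as.numeric(predict(fit, xte))
        cls <- factor(ifelse(score >= 0.5, "tumour", "normal"), levels = lev)
        list(class = cls, score = score)
      }
    )
  })
}

# Pooled cross-validated (or held-out) accuracy of a gene subset. `x` is the
# samples x genes matrix restricted to the subset; `plan` controls folding.
cv_accuracy <- function(x, y, classifier, plan) {
  folds <- if (plan$kind == "kfold") make_split(y, plan) else
    list(make_split(y, plan)$test)
  n_correct <- 0L; n_total <- 0L
  for (test in folds) {
    train <- setdiff(seq_along(y), test)
    out <- fit_predict(classifier, x[train, , drop = FALSE], y[train],
                       x[test, , drop = FALSE], seed = plan$seed)
    n_correct <- n_correct + sum(out$class == y[test])
    n_total <- n_total + length(test)
  }
  n_correct / n_total
}
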