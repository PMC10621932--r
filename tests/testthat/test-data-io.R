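test_that("delimited tables load in either orientation to the same dataset", {
  dir <- withr::local_tempdir()
  rows <- tempfile(tmpdir = dir, fileext = ".csv")
  write.csv(data.frame(sample = c("s1", "s2", "s3"),
                       g1 = c(0.2, 1.5, -0.3),
                       label = c("tumour", "tumour", "normal")),
            rows, row.names = FALSE)
  ds <- load_expression_table(rows, label_column = "label")
  expect_equal(dim(ds$matrix), c(3L, 1L))
  expect_equal(ds$gene_ids, "g1")
  expect_equal(as.character(ds$labels), c("tumour", "tumour", "normal"))

  # transposed table, labels from a separate file
  cols <- tempfile(tmpdir = dir, fileext = ".csv")
  write.csv(data.frame(gene = "g1", s1 = 0.2, s2 = 1.5, s3 = -0.3),
            cols, row.names = FALSE)
  lab <- tempfile(tmpdir = dir, fileext = ".csv")
  write.csv(data.frame(sample = c("s1", "s2", "s3"),
                       label = c("tumour", "tumour", "normal")),
            lab, row.names = FALSE)
  ds2 <- load_expression_table(cols, orientation = "genes-in-rows",
                               label_file = lab)
  expect_equal(ds2$matrix[, 1], ds$matrix[, 1], ignore_attr = TRUE)
  expect_equal(ds2$labels, ds$labels)
})

test_that("loader rejects missing values, bad cells and bad labels", {
  dir <- withr::local_tempdir()
  f <- tempfile(tmpdir = dir, fileext = ".csv")
  write.csv(data.frame(sample = c("s1", "s2"), g1 = c("NA", "1.0"),
                       g2 = c(1, 2), label = c("tumour", "normal")),
            f, row.names = FALSE, quote = FALSE)
  expect_error(load_expression_table(f, label_column = "label"),
               "missing expression value.*s1.*g1")
  # mean imputation fills the hole instead
  ds <- load_expression_table(f, label_column = "label", impute = "mean")
  expect_equal(ds$matrix[1, "g1"], 1.0, ignore_attr = TRUE)

  g <- tempfile(tmpdir = dir, fileext = ".csv")
  write.csv(data.frame(sample = c("s1", "s2"), g1 = c("x", "1.0"),
                       label = c("tumour", "normal")),
            g, row.names = FALSE, quote = FALSE)
  expect_error(load_expression_table(g, label_column = "label"),
               "non-numeric.*s1.*g1")

  h <- tempfile(tmpdir = dir, fileext = ".csv")
  write.csv(data.frame(sample = c("s1", "s2", "s3"), g1 = 1:3,
                       label = c("a", "b", "c")), h, row.names = FALSE)
  expect_error(load_expression_table(h, label_column = "label"),
               "exactly two values")
  expect_error(load_expression_table(h), "labels missing")
})

test_that("duplicate genes are removed first-occurrence-kept", {
  m <- matrix(1:12, 3, 4)
  ds <- expression_dataset(m, c("g1", "g1", "g2", "g1"),
                           labels = c(1, 1, 0))
  out <- remove_duplicate_genes(ds)
  expect_equal(out$gene_ids, c("g1", "g2"))
  expect_equal(attr(out, "n_removed"), 2L)
  expect_equal(out$matrix[, "g1"], m[, 1], ignore_attr = TRUE)

  # no duplicates: identity with 0 removed
  ds2 <- expression_dataset(m, paste0("g", 1:4), labels = c(1, 1, 0))
  out2 <- remove_duplicate_genes(ds2)
  expect_equal(out2$matrix, ds2$matrix)
  expect_equal(attr(out2, "n_removed"), 0L)

  # 5 genes, two duplicated pairs -> 3 kept, 2 removed
  ds3 <- expression_dataset(matrix(rnorm(15), 3, 5),
                            c("a", "b", "a", "c", "b"), labels = c(1, 1, 0))
  out3 <- remove_duplicate_genes(ds3)
  expect_equal(ncol(out3$matrix), 3L)
  expect_equal(attr(out3, "n_removed"), 2L)
})

test_that("z-scoring yields zero mean and unit population variance", {
  ds <- expression_dataset(matrix(c(1, 2, 3), 3, 1), "g1",
                           labels = c(1, 1, 0))
  z <- zscore_normalize(ds)
  expect_equal(z$matrix[, 1], c(-1.224745, 0, 1.224745),
               tolerance = 1e-6, ignore_attr = TRUE)
  # idempotence
  expect_equal(zscore_normalize(z)$matrix, z$matrix, tolerance = 1e-9)
  # constant gene -> zeros with a warning
  dsc <- expression_dataset(cbind(g1 = c(5, 5, 5), g2 = c(1, 2, 4)),
                            labels = c(1, 1, 0))
  expect_warning(zc <- zscore_normalize(dsc), "constant gene")
  expect_equal(zc$matrix[, "g1"], c(0, 0, 0), ignore_attr = TRUE)

  # property: random inputs, population moments within 1e-9
  for (s in 1:5) {
    ds <- make_random_ds(n = 25, g = 12, seed = s)
    z <- zscore_normalize(ds)$matrix
    expect_lt(max(abs(colMeans(z))), 1e-9)
    expect_lt(max(abs(colMeans(sweep(z, 2, colMeans(z)))^2)), 1e-9)
    popvar <- colMeans(z^2) - colMeans(z)^2
    expect_lt(max(abs(popvar - 1)), 1e-9)
  }
})

test_that("dedup then z-score commutes with z-score on the kept genes", {
  set.seed(4)
  m <- matrix(rnorm(40), 5, 8)
  ids <- c("a", "b", "a", "c", "d", "b", "e", "f")
  ds <- expression_dataset(m, ids, labels = c(1, 1, 0, 0, 1))
  a <- zscore_normalize(remove_duplicate_genes(ds))
  kept <- !duplicated(ids)
  b <- zscore_normalize(ds)
  expect_equal(a$matrix, b$matrix[, kept], tolerance = 1e-12)
})

test_that("shuffling permutes rows and labels together, reproducibly", {
  ds <- make_random_ds(n = 36, g = 5, seed = 2)
  # first half all tumour to mimic a class-ordered table
  ds$labels <- factor(rep(c("tumour", "normal"), each = 18),
                      levels = c("normal", "tumour"))
  s1 <- shuffle_samples(ds, seed = 0)
  s2 <- shuffle_samples(ds, seed = 0)
  expect_identical(s1$matrix, s2$matrix)
  expect_identical(s1$labels, s2$labels)
  expect_equal(table(s1$labels), table(ds$labels))
  # positives no longer contiguous
  pos <- which(s1$labels == "tumour")
  expect_gt(max(diff(pos)), 1)
  # pairing preserved under the reported permutation
  perm <- attr(s1, "permutation")
  expect_identical(s1$matrix, ds$matrix[perm, ])
  expect_identical(s1$labels, ds$labels[perm])
})

test_that("holdout split follows the rounding and stratification rules", {
  labs <- factor(rep(c("tumour", "normal"), c(40, 22)),
                 levels = c("normal", "tumour"))
  sp <- make_split(labs, split_plan("holdout", train_fraction = 0.7,
                                    seed = 3))
  expect_length(sp$train, 43)
  expect_length(sp$test, 19)
  expect_setequal(c(sp$train, sp$test), seq_along(labs))
  # per-class proportions preserved within rounding
  expect_equal(sum(labs[sp$test] == "tumour"), 12)
  expect_equal(sum(labs[sp$test] == "normal"), 7)
})

test_that("k-fold splits are balanced, exhaustive and stratification-checked", {
  labs <- factor(rep(c("tumour", "normal"), each = 18),
                 levels = c("normal", "tumour"))
  folds <- make_split(labs, split_plan("kfold", k = 10, seed = 1))
  sizes <- sort(lengths(folds))
  expect_equal(sizes, c(rep(3L, 4), rep(4L, 6)))
  expect_setequal(unlist(folds), 1:36)

  labs10 <- factor(rep(c("tumour", "normal"), each = 5),
                   levels = c("normal", "tumour"))
  f2 <- make_split(labs10, split_plan("kfold", k = 2, seed = 1))
  expect_equal(lengths(f2), c(5L, 5L))

  # property: every index in exactly one fold, sizes differ by <= 1
  for (s in 1:5) {
    n <- sample(20:40, 1)
    labs_r <- factor(rep(c("tumour", "normal"), length.out = n),
                     levels = c("normal", "tumour"))
    k <- sample(2:6, 1)
    fr <- make_split(labs_r, split_plan("kfold", k = k, seed = s))
    expect_equal(sort(unlist(fr)), seq_len(n))
    expect_lte(diff(range(lengths(fr))), 1)
  }

  small <- factor(rep(c("tumour", "normal"), c(3, 15)),
                  levels = c("normal", "tumour"))
  expect_error(make_split(small, split_plan("kfold", k = 5)),
               "fewer than k")
})

test_that("PCA projection matches an independent eigendecomposition", {
  # rank-1 data: first component explains ~100%
  set.seed(7)
  base <- rnorm(10)
  ds <- expression_dataset(cbind(g1 = base, g2 = 2 * base),
                           labels = rep(c(1, 0), 5))
  p <- pca_project(ds, 2)
  expect_gt(p$explained_variance[1], 0.999)
  expect_false(is.unsorted(rev(p$explained_variance)))

  # coordinates match eigen() of the covariance matrix up to sign
  ds3 <- make_random_ds(n = 6, g = 3, seed = 9)
  p3 <- pca_project(ds3, 3)
  x <- scale(ds3$matrix, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(x) / (nrow(x) - 1))
  for (j in 1:3) {
    ref <- x %*% ev$vectors[, j]
    expect_equal(abs(p3$coordinates[, j]), abs(as.numeric(ref)),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_error(pca_project(ds3, 10), "n_components")
})
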