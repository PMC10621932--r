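#' Read a delimited expression table
#'
#' Reads a CSV/TSV expression matrix in either orientation together with the
#' class labels, and returns a validated [expression_dataset()] oriented
#' samples x genes. Labels come either from a named column of the table
#' (samples-in-rows only) or from a separate two-column sample,label file.
#'
#' @param path Path to the delimited expression table (first row = header,
#'   first column = row identifiers). The delimiter is inferred from the
#'   file extension (`.csv` = comma, otherwise tab).
#' @param orientation `"samples-in-rows"` or `"genes-in-rows"`.
#' @param label_column Name of the label column inside the table.
#' @param label_file Path to a two-column (sample id, label) delimited file;
#'   used when labels are not a column of the table.
#' @param positive Label value treated as the tumour class (see
#'   [expression_dataset()]).
#' @param impute `"reject"` (default) fails on missing expression values;
#'   `"mean"` replaces them with the per-gene mean.
#' @return An `expression_dataset`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(sample = c("s1", "s2", "s3"),
#'                      g1 = c(0.2, 1.5, -0.3),
#'                      label = c("tumour", "tumour", "normal")),
#'           f, row.names = FALSE)
#' ds <- load_expression_table(f, label_column = "label")
#' @export
load_expression_table <- function(path,
                                  orientation = c("samples-in-rows",
                                                  "genes-in-rows"),
                                  label_column = NULL, label_file = NULL,
                                  positive = NULL,
                                  impute = c("reject", "mean")) {
  orientation <- match.arg(orientation)
  impute <- match.arg(impute)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("table must have at least two columns", call. = FALSE)
  if (is.null(label_column) && is.null(label_file))
    stop("labels missing: supply label_column or label_file", call. = FALSE)
  row_ids <- as.character(tab[[1]])
  tab <- tab[, -1, drop = FALSE]

  labels <- NULL
  if (!is.null(label_column)) {
    if (orientation != "samples-in-rows")
      stop("label_column requires samples-in-rows orientation; ",
           "use label_file for genes-in-rows tables", call. = FALSE)
    if (!label_column %in% colnames(tab))
      stop("label column '", label_column, "' not found", call. = FALSE)
    labels <- tab[[label_column]]
    tab <- tab[, setdiff(colnames(tab), label_column), drop = FALSE]
  }

  m <- as.matrix(tab)
  bad <- which(is.na(suppressWarnings(apply(tab, 2, as.numeric))) &
               !is.na(as.matrix(tab)), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-numeric expression value at row ", row_ids[bad[1, 1]],
         ", column ", colnames(tab)[bad[1, 2]], call. = FALSE)
  storage.mode(m) <- "double"

  if (orientation == "genes-in-rows") {
    gene_ids <- row_ids
    sample_ids <- colnames(m)
    m <- t(m)
  } else {
    sample_ids <- row_ids
    gene_ids <- colnames(m)
  }
  rownames(m) <- sample_ids
  colnames(m) <- gene_ids

  if (anyNA(m)) {
    if (impute == "reject") {
      bad <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop("missing expression value at sample ", sample_ids[bad[1]],
           ", gene ", gene_ids[bad[2]],
           " (use impute = \"mean\" to impute)", call. = FALSE)
    }
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- mean(m[!nas, j])
    }
  }

  if (is.null(labels)) {
    lsep <- if (grepl("\\.csv$", label_file, ignore.case = TRUE)) "," else "\t"
    ltab <- utils::read.table(label_file, header = TRUE, sep = lsep,
                              stringsAsFactors = FALSE)
    if (ncol(ltab) < 2L)
      stop("label file must have two columns: sample id, label", call. = FALSE)
    idx <- match(sample_ids, as.character(ltab[[1]]))
    if (anyNA(idx))
      stop("label file is missing labels for samples: ",
           paste(utils::head(sample_ids[is.na(idx)], 5), collapse = ", "),
           call. = FALSE)
    labels <- ltab[[2]][idx]
  }

  expression_dataset(m, gene_ids, labels, positive = positive,
                     provenance = path)
}

#' Remove duplicated gene identifiers
#'
#' Keeps the first occurrence of each gene identifier and drops the rest,
#' mirroring the usual first pre-processing step on curated microarray
#' tables where probe identifiers recur. Optionally also collapses genes
#' whose entire expression profile is identical.
#'
#' @param ds An `expression_dataset`.
#' @param by_profile Also drop genes whose expression vector duplicates an
#'   earlier gene's, regardless of identifier.
#' @return The deduplicated dataset, with attribute `"n_removed"` giving the
#'   number of genes dropped.
#' @export
remove_duplicate_genes <- function(ds, by_profile = FALSE) {
  assert_dataset(ds)
  keep <- !duplicated(ds$gene_ids)
  if (by_profile) keep <- keep & !duplicated(t(ds$matrix), MARGIN = 1)
  out <- subset_genes(ds, which(keep))
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Standardize each gene to zero mean and unit variance
#'
#' Per-gene z-scoring with the population variance convention (divide by n).
#' Constant genes cannot be scaled and are mapped to all-zero columns with
#' a warning, so degenerate simulated genes never crash a pipeline.
#'
#' @param ds An `expression_dataset` with at least two samples.
#' @return The normalized dataset.
#' @export
zscore_normalize <- function(ds) {
  assert_dataset(ds)
  n <- nrow(ds$matrix)
  if (n < 2L) stop("z-scoring requires at least two samples", call. = FALSE)
  mu <- colMeans(ds$matrix)
  centered <- sweep(ds$matrix, 2, mu)
  sdev <- sqrt(colMeans(centered^2))  # population sd
  const <- sdev == 0
  if (any(const)) {
    warning(sum(const), " constant gene(s) mapped to zeros during z-scoring",
            call. = FALSE)
    sdev[const] <- 1
  }
  m <- sweep(centered, 2, sdev, "/")
  m[, const] <- 0
  out <- ds
  out$matrix <- m
  out
}

#' Shuffle sample order reproducibly
#'
#' Applies one seeded permutation to the rows of the matrix and to the label
#' vector, so expression/label pairings are preserved. Used to break
#' class-ordered sample layouts before splitting.
#'
#' @param ds An `expression_dataset`.
#' @param seed Integer seed; the permutation is a deterministic function of it.
#' @return The permuted dataset, with attribute `"permutation"` (the row
#'   order applied: output row i is input row `permutation[i]`).
#' @export
shuffle_samples <- function(ds, seed) {
  assert_dataset(ds)
  n <- nrow(ds$matrix)
  perm <- with_seed(derive_seed(seed, "shuffle"), sample.int(n))
  out <- ds
  out$matrix <- ds$matrix[perm, , drop = FALSE]
  out$labels <- ds$labels[perm]
  attr(out, "permutation") <- perm
  out
}

#' Describe a train/test or cross-validation split
#'
#' @param kind `"holdout"` or `"kfold"`.
#' @param train_fraction Fraction of samples used for training under holdout.
#' @param k Number of folds under kfold.
#' @param seed Integer seed controlling the assignment.
#' @param stratified Preserve per-class proportions in every partition.
#' @return A `split_plan` object.
#' @export
split_plan <- function(kind = c("holdout", "kfold"), train_fraction = 0.7,
                       k = 10L, seed = 0L, stratified = TRUE) {
  kind <- match.arg(kind)
  if (kind == "holdout" &&
      (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1))
    stop("train_fraction must lie in (0, 1)", call. = FALSE)
  if (kind == "kfold" && (!is.numeric(k) || k < 2))
    stop("kfold requires k >= 2", call. = FALSE)
  structure(list(kind = kind, train_fraction = train_fraction,
                 k = as.integer(k), seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "split_plan")
}

#' Materialize a split plan into index sets
#'
#' Holdout returns disjoint, exhaustive `train`/`test` index vectors with the
#' test size equal to `round((1 - train_fraction) * n)`; stratified
#' allocation distributes rounding remainders to the larger class first.
#' K-fold returns `k` test folds whose sizes differ by at most one and which
#' partition all sample indices; stratified folds balance each class across
#' folds.
#'
#' @param ds An `expression_dataset` (or a factor of labels).
#' @param plan A [split_plan()].
#' @return For holdout, `list(train =, test =)`; for kfold, a list of `k`
#'   integer vectors (the test folds).
#' @export
make_split <- function(ds, plan) {
  labels <- if (inherits(ds, "expression_dataset")) ds$labels else as.factor(ds)
  if (!inherits(plan, "split_plan")) stop("`plan` must be a split_plan",
                                          call. = FALSE)
  n <- length(labels)
  if (plan$kind == "holdout") make_holdout(labels, plan) else
    make_kfold(labels, plan)
}

make_holdout <- function(labels, plan) {
  n <- length(labels)
  n_test <- round((1 - plan$train_fraction) * n)
  if (n_test < 1L || n_test >= n)
    stop("holdout split leaves an empty partition", call. = FALSE)
  if (!plan$stratified) {
    test <- with_seed(derive_seed(plan$seed, "holdout"),
                      sort(sample.int(n, n_test)))
    return(list(train = setdiff(seq_len(n), test), test = test))
  }
  counts <- table(labels)
  ideal <- (1 - plan$train_fraction) * counts
  quota <- floor(ideal)
  short <- n_test - sum(quota)
  if (short > 0) {
    # remainders decide who gets the extra slots; ties go to the larger class
    ord <- order(-(ideal - quota), -counts)
    quota[ord[seq_len(short)]] <- quota[ord[seq_len(short)]] + 1
  } else if (short < 0) {
    ord <- order(ideal - quota, counts)
    take <- ord[seq_len(-short)]
    quota[take] <- quota[take] - 1
  }
  test <- with_seed(derive_seed(plan$seed, "holdout"), {
    unlist(lapply(names(counts), function(cl) {
      idx <- which(labels == cl)
      sample(idx, quota[[cl]])
    }), use.names = FALSE)
  })
  test <- sort(test)
  list(train = setdiff(seq_len(n), test), test = test)
}

make_kfold <- function(labels, plan) {
  n <- length(labels)
  k <- plan$k
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  if (plan$stratified && any(table(labels) < k))
    stop("stratification impossible: a class has fewer than k members",
         call. = FALSE)
  assign_balanced <- function(idx, offset = 0L) {
    # spread indices over folds round-robin after shuffling, starting at a
    # rotating offset so small classes do not pile onto fold 1
    folds <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    split(idx, folds)[as.character(seq_len(k))]
  }
  with_seed(derive_seed(plan$seed, "kfold"), {
    if (plan$stratified) {
      folds <- rep(list(integer(0)), k)
      offset <- 0L
      for (cl in levels(labels)) {
        idx <- sample(which(labels == cl))
        parts <- assign_balanced(idx, offset)
        offset <- (offset + length(idx)) %% k
        for (f in seq_len(k))
          folds[[f]] <- c(folds[[f]], parts[[f]] %||% integer(0))
      }
      lapply(folds, sort)
    } else {
      idx <- sample.int(n)
      lapply(assign_balanced(idx), sort)
    }
  })
}

#' Project samples onto principal components
#'
#' Thin wrapper over [stats::prcomp()] for exploratory visualization of the
#' sample structure: centers genes, extracts the leading components, and
#' reports the fraction of variance each explains.
#'
#' @param ds An `expression_dataset`.
#' @param n_components Number of components, at most `min(samples, genes)`.
#' @return `list(coordinates =, explained_variance =, rotation =)`.
#' @export
pca_project <- function(ds, n_components = 2L) {
  assert_dataset(ds)
  r <- min(dim(ds$matrix))
  if (n_components > r)
    stop("n_components must be <= min(samples, genes) = ", r, call. = FALSE)
  p <- stats::prcomp(ds$matrix, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  list(coordinates = p$x[, seq_len(n_components), drop = FALSE],
       explained_variance = ev[seq_len(n_components)],
       rotation = p$rotation[, seq_len(n_components), drop = FALSE])
}
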