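#' Construct an expression dataset
#'
#' The container every pipeline stage transforms: a samples x genes numeric
#' matrix, unique gene identifiers, and a binary class label per sample.
#' Tumour is the positive class throughout the package.
#'
#' @param matrix Numeric matrix, samples in rows, genes in columns.
#' @param gene_ids Character vector of gene identifiers, one per column.
#'   Defaults to the matrix column names.
#' @param labels Binary class labels, one per sample. Accepted encodings:
#'   a factor/character with two values, or 0/1. Mapped to a factor with
#'   levels `c("normal", "tumour")` via `positive`.
#' @param positive The label value that denotes the tumour (positive) class.
#'   If `NULL`, `"tumour"`, `"positive"` or `1` is used when present,
#'   otherwise the minority label.
#' @param provenance Free-text source tag.
#' @return An object of class `expression_dataset` with elements `matrix`,
#'   `gene_ids`, `labels` and `provenance`.
#' @examples
#' m <- matrix(rnorm(12), nrow = 4, dimnames = list(NULL, paste0("g", 1:3)))
#' ds <- expression_dataset(m, labels = c(1, 1, 0, 0))
#' dim(ds$matrix)
#' @export
expression_dataset <- function(matrix, gene_ids = colnames(matrix), labels,
                               positive = NULL, provenance = "unspecified") {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("`matrix` must be a numeric matrix (samples x genes)", call. = FALSE)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(matrix)))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != ncol(matrix))
    stop("length(gene_ids) must equal ncol(matrix)", call. = FALSE)
  if (length(labels) != nrow(matrix))
    stop("one label per sample required: ", length(labels), " labels for ",
         nrow(matrix), " samples", call. = FALSE)
  if (anyNA(matrix))
    stop("expression matrix contains missing values", call. = FALSE)
  labels <- map_labels(labels, positive)
  colnames(matrix) <- gene_ids
  structure(
    list(matrix = matrix, gene_ids = gene_ids, labels = labels,
         provenance = provenance),
    class = "expression_dataset"
  )
}

# Map arbitrary two-valued labels to factor(normal/tumour), tumour positive.
map_labels <- function(labels, positive = NULL) {
  if (anyNA(labels)) stop("labels contain missing values", call. = FALSE)
  vals <- unique(as.character(labels))
  if (length(vals) != 2L)
    stop("labels must take exactly two values, got ", length(vals), ": ",
         paste(utils::head(vals, 5), collapse = ", "), call. = FALSE)
  if (is.null(positive)) {
    lower <- tolower(vals)
    hit <- vals[lower %in% c("tumour", "tumor", "positive", "1", "true")]
    positive <- if (length(hit)) hit[1] else vals[which.min(tabulate(
      match(as.character(labels), vals)))]
  }
  positive <- as.character(positive)
  if (!positive %in% vals)
    stop("positive label '", positive, "' not present in labels", call. = FALSE)
  factor(ifelse(as.character(labels) == positive, "tumour", "normal"),
         levels = c("normal", "tumour"))
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("<expression_dataset> ", nrow(x$matrix), " samples x ",
      ncol(x$matrix), " genes\n", sep = "")
  tab <- table(x$labels)
  cat("  labels: tumour=", tab[["tumour"]], " normal=", tab[["normal"]],
      "\n  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$matrix)

# Subset genes (columns) by index, preserving labels and provenance.
subset_genes <- function(ds, idx) {
  expression_dataset(ds$matrix[, idx, drop = FALSE], ds$gene_ids[idx],
                     ds$labels, positive = "tumour",
                     provenance = ds$provenance)
}

# Subset samples (rows) by index.
subset_samples <- function(ds, idx) {
  labs <- ds$labels[idx]
  if (nlevels(droplevels(labs)) < 2L)
    stop("sample subset would drop a class", call. = FALSE)
  expression_dataset(ds$matrix[idx, , drop = FALSE], ds$gene_ids,
                     labs, positive = "tumour", provenance = ds$provenance)
}

assert_dataset <- function(ds) {
  if (!inherits(ds, "expression_dataset"))
    stop("expected an `expression_dataset`", call. = FALSE)
  invisible(ds)
}
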