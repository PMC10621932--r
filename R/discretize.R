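#' Shannon entropy of a categorical vector
#'
#' @param labels Non-empty categorical vector.
#' @return Entropy in bits; `0 * log(0)` contributes zero.
#' @examples
#' entropy(c(1, 1, 0, 0))  # 1 bit
#' @export
entropy <- function(labels) {
  if (length(labels) == 0L) stop("entropy of an empty vector", call. = FALSE)
  p <- tabulate(as.integer(factor(labels)))
  p <- p[p > 0] / length(labels)
  -sum(p * log2(p))
}

# Entropy from a vector of non-negative counts.
entropy_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Discretize one gene's expression values
#'
#' Supervised discretization for entropy-based scoring. The default is the
#' Fayyad-Irani recursive scheme: binary cuts at class-boundary midpoints are
#' accepted only when the information gain of the cut beats its minimum
#' description length cost, so class-independent genes typically collapse to
#' a single bin (and hence zero information gain). `equal_frequency` falls
#' back to unsupervised quantile bins.
#'
#' @param values Finite numeric vector of expression values.
#' @param labels Class labels, same length as `values` (ignored by
#'   `equal_frequency`).
#' @param method `"mdl"` or `"equal_frequency"`.
#' @param bins Bin count for `equal_frequency` (must be >= 2).
#' @return `list(bins = integer bin assignment (1-based), boundaries = cut
#'   points)`. A single bin has no boundaries.
#' @export
discretize_gene <- function(values, labels = NULL,
                            method = c("mdl", "equal_frequency"),
                            bins = 4L) {
  method <- match.arg(method)
  if (!all(is.finite(values)))
    stop("expression values must be finite", call. = FALSE)
  if (method == "mdl") {
    if (is.null(labels) || length(labels) != length(values))
      stop("mdl discretization requires labels matching `values`",
           call. = FALSE)
    cuts <- sort(mdl_cut_points(values, as.integer(factor(labels))))
  } else {
    if (bins < 2L) stop("equal_frequency requires bins >= 2", call. = FALSE)
    qs <- stats::quantile(values, probs = seq_len(bins - 1L) / bins,
                          names = FALSE, type = 7)
    cuts <- unique(qs[qs > min(values) & qs < max(values)])
  }
  assignment <- findInterval(values, cuts, left.open = TRUE) + 1L
  list(bins = assignment, boundaries = cuts)
}

# Fayyad-Irani MDLPC: recursively pick the boundary cut with maximal
# information gain and keep it only if the gain exceeds the MDL cost
#   [log2(N-1) + log2(3^k - 2) - k*E + k1*E1 + k2*E2] / N.
mdl_cut_points <- function(values, classes) {
  ord <- order(values)
  v <- values[ord]; y <- classes[ord]
  recurse <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < 4L) return(numeric(0))
    vv <- v[lo:hi]; yy <- y[lo:hi]
    # candidate cuts: between adjacent distinct values (boundary points only
    # matter, but distinct-value midpoints are a safe superset)
    cand <- which(diff(vv) > 0)
    if (!length(cand)) return(numeric(0))
    counts <- tabulate(yy, nbins = max(y))
    e_all <- entropy_counts(counts)
    k <- sum(counts > 0)
    best_gain <- -Inf; best_i <- NA_integer_
    best_e1 <- best_e2 <- best_k1 <- best_k2 <- NA_real_
    # cumulative class counts along the sorted interval
    cum <- apply(sapply(seq_len(max(y)), function(cl) cumsum(yy == cl)),
                 2, identity)
    if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1)
    for (i in cand) {
      left <- cum[i, ]
      right <- counts - left
      e1 <- entropy_counts(left); e2 <- entropy_counts(right)
      gain <- e_all - (i / n) * e1 - ((n - i) / n) * e2
      if (gain > best_gain + 1e-12) {
        best_gain <- gain; best_i <- i
        best_e1 <- e1; best_e2 <- e2
        best_k1 <- sum(left > 0); best_k2 <- sum(right > 0)
      }
    }
    if (is.na(best_i)) return(numeric(0))
    delta <- log2(3^k - 2) - (k * e_all - best_k1 * best_e1 -
                              best_k2 * best_e2)
    threshold <- (log2(n - 1) + delta) / n
    if (best_gain <= threshold) return(numeric(0))
    cut <- (vv[best_i] + vv[best_i + 1L]) / 2
    c(recurse(lo, lo + best_i - 1L), cut, recurse(lo + best_i, hi))
  }
  recurse(1L, length(v))
}

#' Information gain of a binned feature about the class
#'
#' The reduction in class entropy achieved by partitioning the samples on
#' the feature's bins: `H(y) - sum_b (n_b / n) H(y | bin b)`.
#'
#' @param binned Bin assignment vector.
#' @param labels Class labels, same length.
#' @return Information gain in bits (non-negative up to rounding).
#' @examples
#' information_gain(c(1, 1, 2, 2), c("a", "a", "b", "b"))  # 1 bit
#' @export
information_gain <- function(binned, labels) {
  if (length(binned) != length(labels))
    stop("binned and labels must have the same length", call. = FALSE)
  n <- length(labels)
  h <- entropy(labels)
  y <- as.integer(factor(labels))
  cond <- 0
  for (b in unique(binned)) {
    sel <- binned == b
    cond <- cond + sum(sel) / n * entropy_counts(tabulate(y[sel]))
  }
  h - cond
}

#' Plug-in mutual information between two discrete vectors
#'
#' Estimated from the joint contingency table,
#' `sum_xy p(x, y) log2( p(x, y) / (p(x) p(y)) )`.
#'
#' @param x,y Discrete (binned or categorical) vectors of equal length.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have the same length", call. = FALSE)
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  joint <- table(x, y)
  n <- sum(joint)
  px <- rowSums(joint) / n
  py <- colSums(joint) / n
  p <- joint / n
  terms <- p * log2(p / outer(px, py))
  sum(terms[p > 0])
}

# Discretize every gene of a dataset with the MDL scheme; returns a list of
# bin-assignment vectors plus the boundaries, reused by IG and mRMR scoring.
discretize_dataset <- function(ds, method = "mdl", bins = 4L) {
  lapply(seq_len(ncol(ds$matrix)), function(j)
    discretize_gene(ds$matrix[, j], ds$labels, method = method, bins = bins))
}
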