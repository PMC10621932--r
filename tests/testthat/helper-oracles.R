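# Independent brute-force oracles and tiny dataset builders shared across
# the test files. These deliberately re-derive each quantity from first
# principles (direct summation, exhaustive enumeration) so they stay
# independent of the package's own code paths.

# Shannon entropy by direct summation over the empirical distribution.
oracle_entropy <- function(y) {
  p <- as.numeric(table(y)) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Information gain by direct summation over bins.
oracle_ig <- function(bins, y) {
  n <- length(y)
  cond <- 0
  for (b in unique(bins)) {
    sel <- bins == b
    cond <- cond + sum(sel) / n * oracle_entropy(y[sel])
  }
  oracle_entropy(y) - cond
}

# Mutual information by direct summation over the joint table.
oracle_mi <- function(x, y) {
  n <- length(x)
  tot <- 0
  for (a in unique(x)) for (b in unique(y)) {
    pxy <- sum(x == a & y == b) / n
    if (pxy > 0)
      tot <- tot + pxy * log2(pxy / (sum(x == a) / n * sum(y == b) / n))
  }
  tot
}

# Brute-force re-implementation of the greedy mRMR rule on pre-binned data.
oracle_mrmr <- function(bins_list, y, k, scheme = "MID", eps = 1e-6) {
  G <- length(bins_list)
  rel <- vapply(bins_list, function(b) oracle_mi(b, y), numeric(1))
  sel <- integer(0)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(G), sel)
    s <- vapply(cand, function(g) {
      if (!length(sel)) return(rel[g])
      red <- mean(vapply(sel, function(h) oracle_mi(bins_list[[g]],
                                                    bins_list[[h]]),
                         numeric(1)))
      if (scheme == "MID") rel[g] - red else rel[g] / max(red, eps)
    }, numeric(1))
    sel <- c(sel, cand[which.max(s)])
  }
  sel
}

# AUC by exhaustive enumeration of positive-negative pairs.
oracle_auc <- function(y, s) {
  pos <- which(y == 1); neg <- which(y == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  tot / (length(pos) * length(neg))
}

# A tiny dataset with one perfectly separating gene among noise genes.
make_separable <- function(n = 40, n_noise = 20, seed = 1) {
  set.seed(seed)
  y <- rep(c("tumour", "normal"), each = n / 2)
  m <- cbind(ifelse(y == "tumour", 3, 0) + rnorm(n, sd = 0.3),
             matrix(rnorm(n * n_noise), n, n_noise))
  expression_dataset(m, paste0("g", seq_len(n_noise + 1)), y,
                     positive = "tumour")
}

# A small random (label-independent) dataset.
make_random_ds <- function(n = 30, g = 8, seed = 1) {
  set.seed(seed)
  y <- rep(c("tumour", "normal"), length.out = n)
  expression_dataset(matrix(rnorm(n * g), n, g,
                            dimnames = list(NULL, paste0("g", seq_len(g)))),
                     labels = y, positive = "tumour")
}
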