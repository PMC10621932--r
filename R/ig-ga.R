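#' Genetic-algorithm configuration
#'
#' Conventional defaults for the wrapper search: tournament selection,
#' one-point crossover, per-bit mutation at 1/L, single-elite carry-over and
#' early stopping after `patience` stagnant generations.
#'
#' @param population_size Number of chromosomes (>= 2).
#' @param generations Maximum generations.
#' @param crossover_rate Probability a parent pair is recombined.
#' @param mutation_rate Per-bit flip probability; `NULL` means 1/L where L is
#'   the chromosome length.
#' @param elitism Number of best individuals copied unchanged each generation.
#' @param tournament_size Tournament size for parent selection.
#' @param fitness_size_weight Weight of the parsimony term in the fitness
#'   (0 = pure cross-validated accuracy).
#' @param patience Stop after this many generations without improvement.
#' @param seed Integer seed; the whole search is reproducible from it.
#' @return A `ga_config` object.
#' @export
ga_config <- function(population_size = 50L, generations = 100L,
                      crossover_rate = 0.9, mutation_rate = NULL,
                      elitism = 1L, tournament_size = 3L,
                      fitness_size_weight = 0, patience = 20L, seed = 0L) {
  if (population_size < 2L) stop("population_size must be >= 2", call. = FALSE)
  if (elitism >= population_size)
    stop("elitism must be smaller than population_size", call. = FALSE)
  for (r in c(crossover_rate, fitness_size_weight))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]", call. = FALSE)
  if (!is.null(mutation_rate) && (mutation_rate < 0 || mutation_rate > 1))
    stop("mutation_rate must lie in [0, 1]", call. = FALSE)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism = as.integer(elitism),
                 tournament_size = as.integer(tournament_size),
                 fitness_size_weight = fitness_size_weight,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "ga_config")
}

#' Score genes by information gain and drop the uninformative ones
#'
#' Each gene is discretized (MDL by default) and scored by the information
#' gain of its bins about the class; genes whose gain does not exceed
#' `threshold` are removed. With MDL discretization a class-independent gene
#' usually collapses to a single bin and scores exactly zero, so the default
#' threshold of zero removes it.
#'
#' @param ds An `expression_dataset`.
#' @param threshold Genes with gain <= `threshold` are dropped (default 0).
#' @param method Discretization scheme, `"mdl"` or `"equal_frequency"`.
#' @param bins Bin count for `equal_frequency`.
#' @return `list(dataset = filtered expression_dataset, scores = ig_scores)`,
#'   where `scores` retains the gain, bin boundaries and survival flag for
#'   every original gene, in the original order.
#' @export
ig_filter <- function(ds, threshold = 0, method = "mdl", bins = 4L) {
  assert_dataset(ds)
  disc <- discretize_dataset(ds, method = method, bins = bins)
  gain <- vapply(disc, function(d) information_gain(d$bins, ds$labels),
                 numeric(1))
  keep <- which(gain > threshold)
  if (!length(keep))
    stop("all genes scored <= ", threshold,
         " information gain; lower the threshold or use equal_frequency ",
         "discretization", call. = FALSE)
  scores <- structure(
    list(gene_ids = ds$gene_ids, gain = gain,
         boundaries = lapply(disc, `[[`, "boundaries"),
         kept = seq_along(gain) %in% keep, threshold = threshold),
    class = "ig_scores")
  list(dataset = subset_genes(ds, keep), scores = scores)
}

#' Wrapper fitness of a gene mask
#'
#' The objective both metaheuristics maximize:
#' `(1 - w) * cv_accuracy + w * (1 - |mask| / L)` with `w =
#' size_weight`. The default `size_weight = 0` reproduces pure
#' cross-validated accuracy. An empty mask scores 0 with a warning rather
#' than an error, so population-based search never aborts.
#'
#' @param mask Logical (or 0/1) vector over the dataset's genes.
#' @param ds An `expression_dataset`.
#' @param classifier A [classifier_spec()] or classifier name (default 1-NN).
#' @param protocol A [split_plan()] describing the fitness CV (default
#'   stratified 5-fold).
#' @param size_weight Parsimony weight in `[0, 1]`.
#' @return Fitness in `[0, 1]`.
#' @export
ga_fitness <- function(mask, ds, classifier = classifier_spec("knn", k = 1),
                       protocol = split_plan("kfold", k = 5, seed = 0),
                       size_weight = 0) {
  assert_dataset(ds)
  mask <- as.logical(mask)
  if (length(mask) != ncol(ds$matrix))
    stop("mask length must equal the gene count", call. = FALSE)
  if (!any(mask)) {
    warning("empty gene mask: fitness defined as 0", call. = FALSE)
    return(0)
  }
  acc <- cv_accuracy(ds$matrix[, mask, drop = FALSE], ds$labels,
                     classifier, protocol)
  (1 - size_weight) * acc + size_weight * (1 - mean(mask))
}

# mask comparison used for best-ever bookkeeping: higher fitness wins; ties
# prefer fewer selected genes, then the lexicographically smaller mask.
mask_better <- function(f_a, m_a, f_b, m_b, tol = 1e-12) {
  if (f_a > f_b + tol) return(TRUE)
  if (f_a < f_b - tol) return(FALSE)
  if (sum(m_a) != sum(m_b)) return(sum(m_a) < sum(m_b))
  d <- which(m_a != m_b)
  length(d) > 0 && !m_a[d[1]]
}

# Memoizing fitness evaluator shared by the GA and the PSO. Returns a
# closure; `$count()` reports the number of distinct evaluations.
make_fitness_cache <- function(fitness_fn) {
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  eval_mask <- function(mask) {
    key <- paste0("m", paste(which(mask), collapse = ","))
    if (is.null(cache[[key]])) {
      n_eval <<- n_eval + 1L
      cache[[key]] <- if (any(mask)) fitness_fn(mask) else 0
    }
    cache[[key]]
  }
  list(eval = eval_mask, count = function() n_eval)
}

#' Genetic-algorithm wrapper selection
#'
#' Evolves binary gene masks over the dataset's genes to maximize the
#' wrapper fitness ([ga_fitness()]). Initial masks set each bit with
#' probability `min(0.5, 100 / L)` so first-generation subsets stay small in
#' very high dimension. Selection is by tournament, recombination by
#' one-point crossover, variation by per-bit mutation; the best `elitism`
#' individuals are carried over unchanged. The best-ever individual (ties
#' broken toward smaller subsets) is returned.
#'
#' @inheritParams ga_fitness
#' @param config A [ga_config()].
#' @return A `ga_result`: `best_mask` (logical), `selected` (gene indices),
#'   `gene_ids`, `best_fitness`, `fitness_history` (best-ever per
#'   generation, non-decreasing), `evaluations`, `generations_run`.
#' @export
ga_select <- function(ds, config = ga_config(),
                      classifier = classifier_spec("knn", k = 1),
                      protocol = split_plan("kfold", k = 5,
                                            seed = config$seed)) {
  assert_dataset(ds)
  L <- ncol(ds$matrix)
  if (L < 1L) stop("dataset has no genes", call. = FALSE)
  mut <- config$mutation_rate %||% (1 / L)
  cache <- make_fitness_cache(function(mask)
    ga_fitness(mask, ds, classifier, protocol,
               size_weight = config$fitness_size_weight))

  with_seed(derive_seed(config$seed, "ga"), {
    p0 <- min(0.5, 100 / L)
    pop <- lapply(seq_len(config$population_size),
                  function(i) stats::runif(L) < p0)
    fit <- vapply(pop, cache$eval, numeric(1))

    best_mask <- pop[[which.max(fit)]]
    best_fit <- max(fit)
    for (i in seq_along(pop))
      if (mask_better(fit[i], pop[[i]], best_fit, best_mask)) {
        best_fit <- fit[i]; best_mask <- pop[[i]]
      }

    history <- numeric(0)
    stagnant <- 0L
    gens <- 0L
    tournament <- function() {
      idx <- sample.int(config$population_size,
                        min(config$tournament_size, config$population_size))
      idx[which.max(fit[idx])]
    }
    for (gen in seq_len(config$generations)) {
      gens <- gen
      elite_idx <- order(-fit)[seq_len(config$elitism)]
      nxt <- pop[elite_idx]
      while (length(nxt) < config$population_size) {
        a <- pop[[tournament()]]; b <- pop[[tournament()]]
        if (stats::runif(1) < config$crossover_rate && L > 1) {
          pt <- sample.int(L - 1L, 1L)
          tmp <- a
          a <- c(a[1:pt], b[(pt + 1):L])
          b <- c(b[1:pt], tmp[(pt + 1):L])
        }
        for (child in list(a, b)) {
          flips <- stats::runif(L) < mut
          nxt[[length(nxt) + 1L]] <- xor(child, flips)
          if (length(nxt) >= config$population_size) break
        }
      }
      pop <- nxt
      fit <- vapply(pop, cache$eval, numeric(1))
      improved <- FALSE
      for (i in seq_along(pop))
        if (mask_better(fit[i], pop[[i]], best_fit, best_mask)) {
          improved <- improved || fit[i] > best_fit + 1e-12
          best_fit <- fit[i]; best_mask <- pop[[i]]
        }
      history <- c(history, best_fit)
      stagnant <- if (improved) 0L else stagnant + 1L
      if (stagnant >= config$patience) break
    }

    structure(list(best_mask = best_mask,
                   selected = which(best_mask),
                   gene_ids = ds$gene_ids[best_mask],
                   best_fitness = best_fit,
                   fitness_history = history,
                   evaluations = cache$count(),
                   generations_run = gens),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat("<ga_result> ", length(x$selected), " genes selected, fitness ",
      signif(x$best_fitness, 4), " after ", x$generations_run,
      " generations (", x$evaluations, " evaluations)\n", sep = "")
  invisible(x)
}
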