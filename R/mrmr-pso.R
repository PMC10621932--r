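#' Particle-swarm configuration for binary subset search
#'
#' Constriction-style defaults: inertia 0.729, cognitive and social
#' coefficients 1.49445, velocity clamp 4, with early stopping after
#' `patience` stagnant iterations.
#'
#' @param swarm_size Number of particles (>= 2).
#' @param iterations Maximum iterations.
#' @param w Inertia weight.
#' @param c1,c2 Cognitive and social acceleration coefficients.
#' @param v_max Velocity clamp (positive); bit probabilities are
#'   `sigmoid(v)` with `v` in `[-v_max, v_max]`.
#' @param pool_size Number of top-ranked mRMR candidates exposed to the
#'   swarm in [phase2()].
#' @param patience Stop after this many iterations without gbest improvement.
#' @param seed Integer seed.
#' @return A `pso_config` object.
#' @export
pso_config <- function(swarm_size = 30L, iterations = 100L, w = 0.729,
                       c1 = 1.49445, c2 = 1.49445, v_max = 4,
                       pool_size = 100L, patience = 20L, seed = 0L) {
  if (swarm_size < 2L) stop("swarm_size must be >= 2", call. = FALSE)
  if (v_max <= 0) stop("v_max must be positive", call. = FALSE)
  structure(list(swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations), w = w, c1 = c1,
                 c2 = c2, v_max = v_max, pool_size = as.integer(pool_size),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "pso_config")
}

#' Rank genes by minimum redundancy, maximum relevance
#'
#' Greedy mutual-information ranking: relevance of a gene is its MI with the
#' class; redundancy is its MI with already-selected genes, both estimated
#' from MDL-discretized values. The first pick maximizes relevance; each
#' later pick maximizes `relevance - mean redundancy` (MID) or
#' `relevance / mean redundancy` (MIQ, denominator floored at 1e-6). Ties go
#' to the lower gene index.
#'
#' @param ds An `expression_dataset`.
#' @param k Number of genes to rank (1 <= k <= gene count).
#' @param scheme `"MID"` (difference) or `"MIQ"` (quotient).
#' @param discretization Optional precomputed output of an earlier MDL
#'   discretization (a list of per-gene `bins` vectors), reused to avoid
#'   re-binning.
#' @return An `mrmr_scores` object: `relevance` (per gene, bits),
#'   `selection_order` (ranked gene indices), `greedy_scores` (score at each
#'   pick), `redundancy` (genes x selected MI matrix), `scheme`, `gene_ids`.
#' @export
mrmr_rank <- function(ds, k, scheme = c("MID", "MIQ"),
                      discretization = NULL) {
  assert_dataset(ds)
  scheme <- match.arg(scheme)
  G <- ncol(ds$matrix)
  if (k < 1L || k > G) stop("k must lie in [1, ", G, "]", call. = FALSE)
  disc <- discretization %||% discretize_dataset(ds)
  bins <- lapply(disc, `[[`, "bins")
  y <- ds$labels
  relevance <- vapply(bins, function(b) mutual_information(b, y), numeric(1))

  selected <- integer(0)
  scores <- numeric(0)
  red <- matrix(0, G, 0)  # MI of every gene with each selected gene
  eps <- 1e-6
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(G), selected)
    if (step == 1L) {
      s <- relevance[cand]
    } else {
      mean_red <- rowMeans(red[cand, , drop = FALSE])
      s <- if (scheme == "MID") relevance[cand] - mean_red
           else relevance[cand] / pmax(mean_red, eps)
    }
    pick <- cand[which.max(s)]  # which.max takes the first = lowest index
    selected <- c(selected, pick)
    scores <- c(scores, max(s))
    if (step < k) {
      col <- vapply(seq_len(G), function(g)
        if (g %in% selected) 0 else mutual_information(bins[[g]],
                                                       bins[[pick]]),
        numeric(1))
      red <- cbind(red, col)
    }
  }
  colnames(red) <- ds$gene_ids[selected[seq_len(ncol(red))]]
  structure(list(relevance = relevance, redundancy = red,
                 selection_order = selected, greedy_scores = scores,
                 scheme = scheme, gene_ids = ds$gene_ids),
            class = "mrmr_scores")
}

#' Subset fitness used by the particle swarm
#'
#' Identical contract to [ga_fitness()] with `size_weight = 0`: the pure
#' cross-validated accuracy of the masked gene subset, and 0 (with a
#' warning) for an empty mask.
#'
#' @inheritParams ga_fitness
#' @return Fitness in `[0, 1]`.
#' @export
bpso_fitness <- function(mask, ds, classifier = classifier_spec("knn", k = 1),
                         protocol = split_plan("kfold", k = 5, seed = 0)) {
  ga_fitness(mask, ds, classifier, protocol, size_weight = 0)
}

sigmoid <- function(v) 1 / (1 + exp(-v))

#' Binary particle-swarm subset optimization
#'
#' Standard binary PSO over masks of the candidate genes: real velocities
#' are updated as `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`,
#' clamped to `[-v_max, v_max]`, and each bit is resampled to 1 with
#' probability `sigmoid(v)`. Personal and global bests use the same
#' tie-breaking as the GA (higher fitness, then fewer genes). The search is
#' reproducible from the config seed.
#'
#' @param ds An `expression_dataset`.
#' @param candidates Indices of the genes the swarm may select (the
#'   search space dimension is `length(candidates)`).
#' @param config A [pso_config()].
#' @param classifier,protocol Passed to [bpso_fitness()].
#' @param init_prob Per-candidate probability that an initial particle sets
#'   the bit (recycled; default 0.5). Initial velocities are centred on the
#'   logit of this probability, so the bias persists through the first
#'   resampling steps instead of washing out immediately.
#' @param fitness_fn Optional override: a function of a logical mask over
#'   `candidates` returning a scalar fitness. Used for surrogate objectives;
#'   the default is [bpso_fitness()] on the masked genes.
#' @return `list(subset = feature_subset over the full gene space,
#'   gbest_fitness, gbest_history (non-decreasing), iterations_run,
#'   evaluations)`.
#' @export
bpso_select <- function(ds, candidates, config = pso_config(),
                        classifier = classifier_spec("knn", k = 1),
                        protocol = split_plan("kfold", k = 5,
                                              seed = config$seed),
                        init_prob = 0.5, fitness_fn = NULL) {
  assert_dataset(ds)
  if (!length(candidates)) stop("candidates must be non-empty", call. = FALSE)
  D <- length(candidates)
  init_prob <- rep_len(init_prob, D)
  if (is.null(fitness_fn)) {
    fitness_fn <- function(mask) {
      full <- logical(ncol(ds$matrix))
      full[candidates[mask]] <- TRUE
      if (!any(full)) return(0)
      cv_accuracy(ds$matrix[, full, drop = FALSE], ds$labels, classifier,
                  protocol)
    }
  }
  cache <- make_fitness_cache(fitness_fn)

  with_seed(derive_seed(config$seed, "pso"), {
    S <- config$swarm_size
    x <- matrix(stats::runif(S * D) < rep(init_prob, each = S), S, D)
    p_clamped <- pmin(pmax(init_prob, 1e-3), 1 - 1e-3)
    v0 <- pmin(pmax(log(p_clamped / (1 - p_clamped)), -config$v_max),
               config$v_max)
    v <- matrix(rep(v0, each = S), S, D) +
      matrix(stats::runif(S * D, -1, 1), S, D)
    fit <- apply(x, 1, function(m) cache$eval(as.logical(m)))
    pbest <- x
    pbest_fit <- fit
    gbest_i <- which.max(pbest_fit)
    gbest <- pbest[gbest_i, ]
    gbest_fit <- pbest_fit[gbest_i]
    for (i in seq_len(S))
      if (mask_better(pbest_fit[i], pbest[i, ], gbest_fit, gbest)) {
        gbest <- pbest[i, ]; gbest_fit <- pbest_fit[i]
      }

    history <- numeric(0)
    stagnant <- 0L
    iters <- 0L
    for (it in seq_len(config$iterations)) {
      iters <- it
      r1 <- matrix(stats::runif(S * D), S, D)
      r2 <- matrix(stats::runif(S * D), S, D)
      v <- config$w * v +
        config$c1 * r1 * (pbest - x) +
        config$c2 * r2 * matrix(rep(gbest, each = S) - x, S, D)
      v <- pmin(pmax(v, -config$v_max), config$v_max)
      x <- matrix(stats::runif(S * D), S, D) < sigmoid(v)
      fit <- apply(x, 1, function(m) cache$eval(as.logical(m)))
      improved <- FALSE
      for (i in seq_len(S)) {
        if (mask_better(fit[i], x[i, ], pbest_fit[i], pbest[i, ])) {
          pbest[i, ] <- x[i, ]; pbest_fit[i] <- fit[i]
        }
        if (mask_better(pbest_fit[i], pbest[i, ], gbest_fit, gbest)) {
          improved <- improved || pbest_fit[i] > gbest_fit + 1e-12
          gbest <- pbest[i, ]; gbest_fit <- pbest_fit[i]
        }
      }
      history <- c(history, gbest_fit)
      stagnant <- if (improved) 0L else stagnant + 1L
      if (stagnant >= config$patience) break
    }

    idx <- sort(candidates[as.logical(gbest)])
    list(subset = feature_subset(idx, ds$gene_ids[idx], phase = "pso"),
         gbest_fitness = gbest_fit, gbest_history = history,
         iterations_run = iters, evaluations = cache$count())
  })
}

#' An ordered set of selected genes with provenance
#'
#' @param indices Integer gene indices (into the dataset the producing stage
#'   saw).
#' @param gene_ids Matching gene identifiers.
#' @param phase Free-text tag of the producing stage.
#' @return A `feature_subset` object.
#' @export
feature_subset <- function(indices, gene_ids, phase = "manual") {
  if (length(indices) != length(gene_ids))
    stop("indices and gene_ids must have equal length", call. = FALSE)
  structure(list(indices = as.integer(indices),
                 gene_ids = as.character(gene_ids), phase = phase),
            class = "feature_subset")
}

#' @export
print.feature_subset <- function(x, ...) {
  cat("<feature_subset> ", length(x$indices), " genes (", x$phase, "): ",
      paste(utils::head(x$gene_ids, 8), collapse = ", "),
      if (length(x$gene_ids) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Phase 2: mRMR ranking followed by particle-swarm refinement
#'
#' Ranks the phase-1 genes by [mrmr_rank()], exposes the top `pool_size`
#' ranks to the swarm as candidates, and initializes particles with a bias
#' toward higher-ranked genes: the initial bit probability decays
#' exponentially with rank, `p_r = 0.9 exp(-(r - 1) / 8)`, so initial
#' particles concentrate on the least-redundant high-relevance genes and
#' the swarm's job is to trim and locally amend that core. With a singleton
#' pool the swarm is degenerate and the top-ranked gene is returned
#' directly.
#'
#' @param ds_phase1 The phase-1 output `expression_dataset`.
#' @param config A [pso_config()]; its `pool_size` caps the candidate pool
#'   and is clipped (with a warning) to the phase-1 gene count.
#' @param scheme mRMR scheme, `"MID"` or `"MIQ"`.
#' @param classifier,protocol Fitness settings, as in [bpso_select()].
#' @return `list(subset = feature_subset (indices into `ds_phase1`),
#'   mrmr = mrmr_scores, pso = bpso_select output or NULL when degenerate)`.
#' @export
phase2 <- function(ds_phase1, config = pso_config(), scheme = "MID",
                   classifier = classifier_spec("knn", k = 1),
                   protocol = split_plan("kfold", k = 5,
                                         seed = config$seed)) {
  assert_dataset(ds_phase1)
  G <- ncol(ds_phase1$matrix)
  pool <- config$pool_size
  if (pool > G) {
    warning("pool_size ", pool, " exceeds the phase-1 gene count ", G,
            "; clipped", call. = FALSE)
    pool <- G
  }
  scores <- mrmr_rank(ds_phase1, k = pool, scheme = scheme)
  candidates <- scores$selection_order
  if (pool == 1L) {
    idx <- candidates[1]
    return(list(subset = feature_subset(idx, ds_phase1$gene_ids[idx],
                                        phase = "mrmr-pso"),
                mrmr = scores, pso = NULL))
  }
  init_prob <- 0.9 * exp(-(seq_len(pool) - 1) / 8)
  res <- bpso_select(ds_phase1, candidates, config, classifier, protocol,
                     init_prob = init_prob)
  res$subset$phase <- "mrmr-pso"
  list(subset = res$subset, mrmr = scores, pso = res)
}
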