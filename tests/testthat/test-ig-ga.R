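test_that("information-gain filtering keeps exactly the discriminative genes", {
  # one gene mirrors the labels, the rest are constant
  y <- rep(c("tumour", "normal"), each = 6)
  m <- cbind(g1 = rep(c(0, 0), 6), g2 = ifelse(y == "tumour", 5, -5),
             g3 = rep(1, 12))
  ds <- expression_dataset(m, labels = y, positive = "tumour")
  out <- ig_filter(ds)
  expect_equal(out$dataset$gene_ids, "g2")
  expect_equal(length(out$scores$gain), 3)
  expect_true(out$scores$kept[2])

  # threshold below zero keeps everything
  ds2 <- make_random_ds(n = 20, g = 6, seed = 3)
  all_kept <- ig_filter(ds2, threshold = -1)
  expect_equal(all_kept$dataset$gene_ids, ds2$gene_ids)

  # surviving gene order is preserved
  out3 <- generate_expression(synthetic_spec(80, 40, n_informative = 6,
                                             effect_size = 2.5, seed = 2))
  f3 <- ig_filter(out3$dataset)
  expect_identical(f3$dataset$gene_ids,
                   out3$dataset$gene_ids[f3$scores$kept])

  # all-constant data cannot pass the filter
  dsc <- expression_dataset(matrix(1, 8, 3), paste0("g", 1:3),
                            labels = rep(c(1, 0), 4))
  expect_error(ig_filter(dsc), "threshold")
})

test_that("planted informative genes survive the zero-IG filter", {
  out <- kentridge_like(seed = 0)
  f <- ig_filter(out$dataset)
  surv <- which(f$scores$kept)
  # oracle: recompute IG per planted gene directly
  for (j in out$truth$informative_indices) {
    d <- discretize_gene(out$dataset$matrix[, j], out$dataset$labels)
    expect_gt(oracle_ig(d$bins, out$dataset$labels), 0)
  }
  expect_true(all(out$truth$informative_indices %in% surv))
})

test_that("wrapper fitness behaves at its boundary cases", {
  ds <- make_separable(n = 40, n_noise = 10, seed = 1)
  prot <- split_plan("kfold", k = 5, seed = 0)
  mask <- c(TRUE, rep(FALSE, 10))
  expect_equal(ga_fitness(mask, ds, protocol = prot), 1.0)
  expect_warning(f0 <- ga_fitness(rep(FALSE, 11), ds, protocol = prot),
                 "empty")
  expect_equal(f0, 0)
  # size_weight discounts larger masks
  full <- rep(TRUE, 11)
  expect_lt(ga_fitness(full, ds, protocol = prot, size_weight = 0.5),
            ga_fitness(mask, ds, protocol = prot, size_weight = 0.5))
  expect_error(ga_fitness(c(TRUE, TRUE), ds), "mask length")
})

test_that("the full mask is never much better than the planted optimum", {
  out <- generate_expression(synthetic_spec(60, 25, n_informative = 5,
                                            effect_size = 2, seed = 4))
  ds <- out$dataset
  prot <- split_plan("kfold", k = 5, seed = 1)
  optimal <- seq_len(25) %in% out$truth$informative_indices
  f_opt <- ga_fitness(optimal, ds, protocol = prot)
  f_full <- ga_fitness(rep(TRUE, 25), ds, protocol = prot)
  expect_lte(f_full, f_opt + 0.05)
})

test_that("GA finds a perfectly separating gene and keeps history monotone", {
  ds <- make_separable(n = 40, n_noise = 20, seed = 1)
  r <- ga_select(ds, ga_config(population_size = 30, generations = 40,
                               seed = 1))
  expect_true(1 %in% r$selected)
  expect_equal(r$best_fitness, 1.0)
  expect_false(is.unsorted(r$fitness_history))
  expect_equal(r$best_fitness,
               ga_fitness(r$best_mask, ds,
                          protocol = split_plan("kfold", k = 5, seed = 1)))
})

test_that("GA without variation operators is static", {
  ds <- make_random_ds(n = 20, g = 5, seed = 8)
  r <- ga_select(ds, ga_config(population_size = 4, generations = 10,
                               crossover_rate = 0, mutation_rate = 0,
                               patience = 100, seed = 2))
  expect_true(all(r$fitness_history == r$fitness_history[1]))
})

test_that("GA runs are bit-identical under a fixed seed", {
  ds <- make_separable(n = 30, n_noise = 8, seed = 5)
  cfg <- ga_config(population_size = 12, generations = 10, seed = 42)
  r1 <- ga_select(ds, cfg)
  r2 <- ga_select(ds, cfg)
  expect_identical(r1$best_mask, r2$best_mask)
  expect_identical(r1$fitness_history, r2$fitness_history)
  expect_identical(r1$evaluations, r2$evaluations)
})

test_that("equal-fitness masks tie-break toward fewer genes", {
  # two genes duplicate each other; a mask with either one has the same
  # fitness as the mask with both, so the smaller mask must win
  y <- rep(c("tumour", "normal"), each = 10)
  set.seed(6)
  g <- ifelse(y == "tumour", 2, -2) + rnorm(20, sd = 0.2)
  ds <- expression_dataset(cbind(g1 = g, g2 = g, g3 = rnorm(20)),
                           labels = y, positive = "tumour")
  r <- ga_select(ds, ga_config(population_size = 20, generations = 30,
                               seed = 3))
  expect_equal(r$best_fitness, 1.0)
  expect_length(r$selected, 1)
})
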