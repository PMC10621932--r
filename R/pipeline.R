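#' Assemble and validate a pipeline run configuration
#'
#' Builds the configuration consumed by [run_full()] and [run_stage()] from
#' a YAML file or nested list. Every key is validated against the published
#' schema below; unknown keys are rejected so typos never silently change a
#' run.
#'
#' Schema (defaults in parentheses):
#' \itemize{
#'   \item `io`: `path`, `orientation` ("samples-in-rows"), `label_column`,
#'     `label_file`, `positive`, `impute` ("reject")
#'   \item `normalize`: `enabled` (TRUE), `dedup` (TRUE), `shuffle` (TRUE)
#'   \item `phase1`: `ig_threshold` (0), `discretization` ("mdl"),
#'     `classifier` ("knn"), `cv_k` (5), plus any [ga_config()] field under
#'     `ga`
#'   \item `phase2`: `enabled` (TRUE), `scheme` ("MID"), `classifier`
#'     ("knn"), `cv_k` (5), plus any [pso_config()] field under `pso`
#'   \item `eval`: `classifiers` (svm nb dt rf knn mlp), `split` ("holdout"),
#'     `train_fraction` (0.7), `k` (10), `stratified` (TRUE)
#'   \item `seed` (0), `out` (NULL = no files written)
#' }
#'
#' @param config Path to a YAML file, or a nested list of overrides.
#' @return A validated `run_config` list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    io = list(path = NULL, orientation = "samples-in-rows",
              label_column = NULL, label_file = NULL, positive = NULL,
              impute = "reject"),
    normalize = list(enabled = TRUE, dedup = TRUE, shuffle = TRUE),
    phase1 = list(ig_threshold = 0, discretization = "mdl",
                  classifier = "knn", cv_k = 5L, ga = list()),
    phase2 = list(enabled = TRUE, scheme = "MID", classifier = "knn",
                  cv_k = 5L, pso = list()),
    eval = list(classifiers = c("svm", "nb", "dt", "rf", "knn", "mlp"),
                split = "holdout", train_fraction = 0.7, k = 10L,
                stratified = TRUE),
    seed = 0L, out = NULL)
  check_keys <- function(given, allowed, where) {
    bad <- setdiff(names(given), names(allowed))
    if (length(bad))
      stop("unknown config key", if (length(bad) > 1) "s", " in ", where,
           ": ", paste(bad, collapse = ", "), call. = FALSE)
  }
  check_keys(config, defaults, "top level")
  for (block in intersect(names(config), c("io", "normalize", "phase1",
                                           "phase2", "eval")))
    check_keys(config[[block]], defaults[[block]], block)
  if (!is.null(config$phase1$ga))
    check_keys(config$phase1$ga, formals(ga_config), "phase1$ga")
  if (!is.null(config$phase2$pso))
    check_keys(config$phase2$pso, formals(pso_config), "phase2$pso")
  cfg <- utils::modifyList(defaults, config)
  structure(cfg, class = "run_config")
}

build_eval_plan <- function(cfg) {
  if (cfg$eval$split == "holdout")
    split_plan("holdout", train_fraction = cfg$eval$train_fraction,
               seed = derive_seed(cfg$seed, "eval-split"),
               stratified = cfg$eval$stratified)
  else
    split_plan("kfold", k = cfg$eval$k,
               seed = derive_seed(cfg$seed, "eval-split"),
               stratified = cfg$eval$stratified)
}

#' Phase 1: information-gain filtering plus GA wrapper selection
#'
#' Convenience composition of [ig_filter()] and [ga_select()]: genes with no
#' information gain about the class are dropped, then the wrapper search
#' picks the best-classifying subset of the survivors.
#'
#' @param ds An `expression_dataset`.
#' @param ig_threshold Gain threshold for [ig_filter()].
#' @param config A [ga_config()].
#' @param classifier,protocol Wrapper fitness settings (see [ga_fitness()]).
#' @param discretization Discretization scheme for the IG scores.
#' @return `list(subset = feature_subset (indices into `ds`),
#'   dataset = selected expression_dataset, ig = ig_scores,
#'   ga = ga_result, survivors = post-filter gene indices)`.
#' @export
phase1 <- function(ds, ig_threshold = 0, config = ga_config(),
                   classifier = classifier_spec("knn", k = 1),
                   protocol = split_plan("kfold", k = 5,
                                         seed = config$seed),
                   discretization = "mdl") {
  filtered <- ig_filter(ds, threshold = ig_threshold,
                        method = discretization)
  ga <- ga_select(filtered$dataset, config, classifier, protocol)
  survivors <- which(filtered$scores$kept)
  idx <- survivors[ga$selected]
  list(subset = feature_subset(idx, ds$gene_ids[idx], phase = "ig-ga"),
       dataset = subset_genes(ds, idx), ig = filtered$scores, ga = ga,
       survivors = survivors)
}

#' Run the full two-phase selection pipeline
#'
#' Executes load, duplicate removal, z-score normalization, seeded sample
#' shuffling, phase 1 (information gain + GA wrapper), a per-phase
#' classifier evaluation, and phase 2 (mRMR + binary PSO). All stage
#' artifacts are written as plain CSV/TSV/JSON files when `out` is set, and
#' the run is byte-reproducible from the config seed.
#'
#' @param config A [run_config()] (or list / YAML path coercible to one).
#' @param dataset Optional in-memory `expression_dataset`; when supplied the
#'   `io` block is ignored.
#' @return A `run_report` list: input summary, per-stage gene counts and
#'   reduction percentages, phase gene lists, per-phase evaluation reports,
#'   elapsed seconds per stage, and the config echo.
#' @export
run_full <- function(config = list(), dataset = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  out_dir <- cfg$out
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  elapsed <- list()
  clock <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- expr
    list(value = v, secs = proc.time()[["elapsed"]] - t0)
  }
  stage <- function(name, expr) {
    r <- tryCatch(clock(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    elapsed[[name]] <<- round(r$secs, 3)
    r$value
  }

  ds <- stage("load", {
    if (!is.null(dataset)) dataset
    else if (!is.null(cfg$io$path))
      load_expression_table(cfg$io$path, orientation = cfg$io$orientation,
                            label_column = cfg$io$label_column,
                            label_file = cfg$io$label_file,
                            positive = cfg$io$positive,
                            impute = cfg$io$impute)
    else stop("no dataset: supply `dataset` or io$path")
  })
  n_input <- ncol(ds$matrix)
  input_summary <- list(samples = nrow(ds$matrix), genes = n_input,
                        tumour = sum(ds$labels == "tumour"),
                        normal = sum(ds$labels == "normal"))

  n_dupes <- 0L
  if (isTRUE(cfg$normalize$dedup)) {
    ds <- stage("dedup", remove_duplicate_genes(ds))
    n_dupes <- attr(ds, "n_removed")
  }
  if (isTRUE(cfg$normalize$enabled)) ds <- stage("normalize",
                                                 zscore_normalize(ds))
  if (isTRUE(cfg$normalize$shuffle))
    ds <- stage("shuffle", shuffle_samples(ds, derive_seed(cfg$seed,
                                                           "shuffle")))

  eval_plan <- build_eval_plan(cfg)
  ga_cfg <- do.call(ga_config, utils::modifyList(
    list(seed = derive_seed(cfg$seed, "ga")), cfg$phase1$ga))
  p1_protocol <- split_plan("kfold", k = cfg$phase1$cv_k,
                            seed = derive_seed(cfg$seed, "fitness-cv"))
  p1 <- stage("phase1", phase1(ds, ig_threshold = cfg$phase1$ig_threshold,
                               config = ga_cfg,
                               classifier = cfg$phase1$classifier,
                               protocol = p1_protocol,
                               discretization = cfg$phase1$discretization))
  report1 <- stage("evaluate_phase1",
                   evaluate_classifiers(ds, p1$subset,
                                        classifiers = cfg$eval$classifiers,
                                        plan = eval_plan, seed = cfg$seed))

  counts <- list(input = n_input, deduplicated = ncol(ds$matrix),
                 ig_survivors = length(p1$survivors),
                 phase1 = length(p1$subset$indices))
  reductions <- list(
    phase1 = reduction_percentage(n_input, counts$phase1))

  p2 <- NULL; report2 <- NULL
  if (isTRUE(cfg$phase2$enabled)) {
    pso_cfg <- do.call(pso_config, utils::modifyList(
      list(seed = derive_seed(cfg$seed, "pso")), cfg$phase2$pso))
    pso_cfg$pool_size <- min(pso_cfg$pool_size, ncol(p1$dataset$matrix))
    p2_protocol <- split_plan("kfold", k = cfg$phase2$cv_k,
                              seed = derive_seed(cfg$seed, "fitness-cv"))
    p2 <- stage("phase2", phase2(p1$dataset, config = pso_cfg,
                                 scheme = cfg$phase2$scheme,
                                 classifier = cfg$phase2$classifier,
                                 protocol = p2_protocol))
    # phase-2 indices are into the phase-1 dataset; lift to the full space
    full_idx <- p1$subset$indices[p2$subset$indices]
    p2$subset <- feature_subset(full_idx, ds$gene_ids[full_idx],
                                phase = "mrmr-pso")
    report2 <- stage("evaluate_phase2",
                     evaluate_classifiers(ds, p2$subset,
                                          classifiers = cfg$eval$classifiers,
                                          plan = eval_plan, seed = cfg$seed))
    counts$phase2 <- length(p2$subset$indices)
    reductions$phase2 <- reduction_percentage(n_input, counts$phase2)
  }

  report <- structure(list(
    input = input_summary, duplicates_removed = n_dupes, counts = counts,
    reductions = reductions,
    phase1_genes = p1$subset$gene_ids,
    phase2_genes = if (!is.null(p2)) p2$subset$gene_ids,
    evaluation_phase1 = report1, evaluation_phase2 = report2,
    phase1_result = p1, phase2_result = p2,
    elapsed = elapsed, seed = cfg$seed, config = unclass(cfg)),
    class = "run_report")
  if (!is.null(out_dir)) write_run_artifacts(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", x$input$samples, " samples, ", x$input$genes,
      " genes (", x$input$tumour, " tumour / ", x$input$normal,
      " normal)\n", sep = "")
  cat("  phase 1: ", x$counts$phase1, " genes (",
      x$reductions$phase1, "% reduction)\n", sep = "")
  if (!is.null(x$counts$phase2))
    cat("  phase 2: ", x$counts$phase2, " genes (",
        x$reductions$phase2, "% reduction)\n", sep = "")
  invisible(x)
}

write_run_artifacts <- function(report, dir) {
  writeLines(report$phase1_genes, file.path(dir, "phase1_genes.txt"))
  ig <- report$phase1_result$ig
  utils::write.table(
    data.frame(gene_id = ig$gene_ids, gain = ig$gain,
               n_bins = vapply(ig$boundaries, length, integer(1)) + 1L,
               kept = ig$kept),
    file.path(dir, "ig_scores.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  ga <- report$phase1_result$ga
  jsonlite::write_json(
    list(selected = ga$gene_ids, best_fitness = ga$best_fitness,
         fitness_history = ga$fitness_history,
         evaluations = ga$evaluations,
         generations_run = ga$generations_run),
    file.path(dir, "ga_result.json"), auto_unbox = TRUE, digits = NA)
  write_report(report$evaluation_phase1,
               tsv = file.path(dir, "report_phase1.tsv"),
               json = file.path(dir, "report_phase1.json"))
  if (!is.null(report$phase2_result)) {
    writeLines(report$phase2_genes, file.path(dir, "phase2_genes.txt"))
    sc <- report$phase2_result$mrmr
    utils::write.table(
      data.frame(rank = seq_along(sc$selection_order),
                 gene_id = sc$gene_ids[sc$selection_order],
                 relevance = sc$relevance[sc$selection_order],
                 greedy_score = sc$greedy_scores),
      file.path(dir, "mrmr_table.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    if (!is.null(report$phase2_result$pso))
      jsonlite::write_json(
        list(gbest_fitness = report$phase2_result$pso$gbest_fitness,
             gbest_history = report$phase2_result$pso$gbest_history,
             iterations_run = report$phase2_result$pso$iterations_run,
             evaluations = report$phase2_result$pso$evaluations),
        file.path(dir, "pso_trace.json"), auto_unbox = TRUE, digits = NA)
    write_report(report$evaluation_phase2,
                 tsv = file.path(dir, "report_phase2.tsv"),
                 json = file.path(dir, "report_phase2.json"))
  }
  jsonlite::write_json(
    list(input = report$input, duplicates_removed = report$duplicates_removed,
         counts = report$counts, reductions = report$reductions,
         elapsed = report$elapsed, seed = report$seed),
    file.path(dir, "run_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# ---- resumable stage execution ----------------------------------------

manifest_path <- function(dir) file.path(dir, "manifest.json")

read_manifest <- function(dir) {
  p <- manifest_path(dir)
  if (file.exists(p)) jsonlite::read_json(p) else list()
}

write_manifest <- function(dir, manifest) {
  jsonlite::write_json(manifest, manifest_path(dir), auto_unbox = TRUE)
}

stage_outputs <- list(
  simulate = c("expression.csv", "labels.csv", "truth.json"),
  phase1 = c("phase1_genes.txt", "ig_scores.tsv", "ga_result.json"),
  phase2 = c("phase2_genes.txt", "mrmr_table.tsv"),
  evaluate = c("report_final.tsv", "report_final.json"))

hash_files <- function(paths) {
  paths <- paths[file.exists(paths)]
  stats::setNames(as.list(tools::md5sum(paths)), basename(paths))
}

#' Run (or resume) one pipeline stage against on-disk artifacts
#'
#' Stages communicate exclusively through plain files in `config$out`, so
#' each one is independently inspectable and re-runnable. A manifest of
#' content hashes makes re-execution a no-op when a stage's inputs and
#' outputs are unchanged, and turns silent corruption of an upstream
#' artifact into an explicit hash-mismatch error.
#'
#' Stages: `"simulate"` (write a synthetic dataset), `"phase1"`,
#' `"phase2"`, `"evaluate"` (evaluate the most recent phase's genes).
#'
#' @param stage Stage name.
#' @param config A [run_config()] with a non-`NULL` `out` directory.
#' @param synthetic A [synthetic_spec()], required by the simulate stage.
#' @return Invisibly, the stage's primary artifact path.
#' @export
run_stage <- function(stage = c("simulate", "phase1", "phase2", "evaluate"),
                      config = list(), synthetic = NULL) {
  stage <- match.arg(stage)
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir <- cfg$out
  if (is.null(dir)) stop("run_stage requires config$out", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- read_manifest(dir)

  inputs <- switch(stage,
    simulate = character(0),
    phase1 = {
      p <- cfg$io$path %||% file.path(dir, "expression.csv")
      if (!file.exists(p))
        stop("phase1 prerequisite missing: no expression table at ", p,
             "; run the simulate stage (or set io$path) first",
             call. = FALSE)
      p
    },
    phase2 = ,
    evaluate = {
      p <- file.path(dir, "phase1_genes.txt")
      if (!file.exists(p))
        stop(stage, " prerequisite missing: run phase1 first", call. = FALSE)
      p
    })

  # verify recorded hashes of prerequisite artifacts
  for (f in inputs) {
    recorded <- manifest$hashes[[basename(f)]]
    if (!is.null(recorded) && recorded != as.character(tools::md5sum(f)))
      stop("hash mismatch for ", basename(f),
           ": artifact changed since it was produced; re-run its stage",
           call. = FALSE)
  }

  outs <- file.path(dir, stage_outputs[[stage]])
  state_key <- jsonlite::toJSON(list(inputs = hash_files(inputs),
                                     seed = cfg$seed), auto_unbox = TRUE)
  if (identical(manifest$stages[[stage]], as.character(state_key)) &&
      all(file.exists(outs))) {
    message("stage ", stage, ": skipped (up to date)")
    return(invisible(outs[1]))
  }

  if (stage == "simulate") {
    if (is.null(synthetic))
      stop("simulate requires a synthetic_spec", call. = FALSE)
    write_synthetic(generate_expression(synthetic), dir)
  } else {
    ds <- load_expression_table(
      cfg$io$path %||% file.path(dir, "expression.csv"),
      orientation = cfg$io$orientation,
      label_column = cfg$io$label_column,
      label_file = if (is.null(cfg$io$path))
        file.path(dir, "labels.csv") else cfg$io$label_file,
      positive = cfg$io$positive, impute = cfg$io$impute)
    if (isTRUE(cfg$normalize$dedup)) ds <- remove_duplicate_genes(ds)
    if (isTRUE(cfg$normalize$enabled)) ds <- zscore_normalize(ds)
    if (isTRUE(cfg$normalize$shuffle))
      ds <- shuffle_samples(ds, derive_seed(cfg$seed, "shuffle"))
    if (stage == "phase1") {
      ga_cfg <- do.call(ga_config, utils::modifyList(
        list(seed = derive_seed(cfg$seed, "ga")), cfg$phase1$ga))
      p1 <- phase1(ds, ig_threshold = cfg$phase1$ig_threshold,
                   config = ga_cfg, classifier = cfg$phase1$classifier,
                   protocol = split_plan("kfold", k = cfg$phase1$cv_k,
                                         seed = derive_seed(cfg$seed,
                                                            "fitness-cv")),
                   discretization = cfg$phase1$discretization)
      writeLines(p1$subset$gene_ids, file.path(dir, "phase1_genes.txt"))
      ig <- p1$ig
      utils::write.table(
        data.frame(gene_id = ig$gene_ids, gain = ig$gain,
                   n_bins = vapply(ig$boundaries, length, integer(1)) + 1L),
        file.path(dir, "ig_scores.tsv"), sep = "\t", row.names = FALSE,
        quote = FALSE)
      jsonlite::write_json(
        list(selected = p1$subset$gene_ids,
             best_fitness = p1$ga$best_fitness,
             fitness_history = p1$ga$fitness_history),
        file.path(dir, "ga_result.json"), auto_unbox = TRUE, digits = NA)
    } else {
      genes1 <- readLines(file.path(dir, "phase1_genes.txt"))
      ds1 <- subset_genes(ds, match(genes1, ds$gene_ids))
      if (stage == "phase2") {
        pso_cfg <- do.call(pso_config, utils::modifyList(
          list(seed = derive_seed(cfg$seed, "pso")), cfg$phase2$pso))
        pso_cfg$pool_size <- min(pso_cfg$pool_size, ncol(ds1$matrix))
        p2 <- phase2(ds1, config = pso_cfg, scheme = cfg$phase2$scheme,
                     classifier = cfg$phase2$classifier,
                     protocol = split_plan("kfold", k = cfg$phase2$cv_k,
                                           seed = derive_seed(cfg$seed,
                                                              "fitness-cv")))
        writeLines(p2$subset$gene_ids, file.path(dir, "phase2_genes.txt"))
        sc <- p2$mrmr
        utils::write.table(
          data.frame(rank = seq_along(sc$selection_order),
                     gene_id = sc$gene_ids[sc$selection_order],
                     relevance = sc$relevance[sc$selection_order],
                     greedy_score = sc$greedy_scores),
          file.path(dir, "mrmr_table.tsv"), sep = "\t", row.names = FALSE,
          quote = FALSE)
      } else {
        genes_path <- file.path(dir, "phase2_genes.txt")
        genes <- if (file.exists(genes_path)) readLines(genes_path) else
          genes1
        rep_ <- evaluate_classifiers(ds, genes,
                                     classifiers = cfg$eval$classifiers,
                                     plan = build_eval_plan(cfg),
                                     seed = cfg$seed)
        write_report(rep_, tsv = file.path(dir, "report_final.tsv"),
                     json = file.path(dir, "report_final.json"))
      }
    }
  }

  manifest$stages[[stage]] <- as.character(state_key)
  manifest$hashes <- utils::modifyList(manifest$hashes %||% list(),
                                       hash_files(outs))
  write_manifest(dir, manifest)
  invisible(outs[1])
}
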