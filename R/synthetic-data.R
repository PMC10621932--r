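#' Specify a synthetic microarray dataset
#'
#' Describes a planted-signal expression dataset: a minority of informative
#' genes whose class-conditional means differ by `effect_size` standard
#' deviations, optional redundant genes (noisy copies of informative
#' parents), and pure-noise filler genes. This is the ground-truth substrate
#' the selection pipeline is tested against.
#'
#' @param n_samples Number of samples.
#' @param n_genes Total number of genes.
#' @param n_informative Number of class-informative genes.
#' @param n_redundant Number of redundant genes, each a noisy copy of a
#'   randomly chosen informative parent. Requires `n_informative >= 1`.
#' @param effect_size Standardized difference d between class means of an
#'   informative gene (in units of `noise_sd`).
#' @param class_balance Fraction of samples in the tumour (positive) class.
#' @param noise_sd Standard deviation of the within-class expression noise.
#' @param redundant_noise_sd Standard deviation of the extra noise added to a
#'   parent to form a redundant copy.
#' @param seed Integer root seed; generation is fully reproducible from it.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_samples, n_genes, n_informative = 0L,
                           n_redundant = 0L, effect_size = 2,
                           class_balance = 0.5, noise_sd = 1,
                           redundant_noise_sd = 0.3, seed = 0L) {
  if (n_informative + n_redundant > n_genes)
    stop("n_informative + n_redundant must not exceed n_genes", call. = FALSE)
  if (n_redundant > 0 && n_informative == 0)
    stop("redundant genes need an informative parent", call. = FALSE)
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  if (class_balance <= 0 || class_balance >= 1)
    stop("class_balance must lie in (0, 1)", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (n_samples < 4) stop("need at least 4 samples", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_informative = as.integer(n_informative),
                 n_redundant = as.integer(n_redundant),
                 effect_size = effect_size, class_balance = class_balance,
                 noise_sd = noise_sd, redundant_noise_sd = redundant_noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic expression dataset with known ground truth
#'
#' Informative genes are class-conditional Gaussians: tumour samples are
#' shifted by `effect_size * noise_sd` relative to normals. Redundant genes
#' equal their parent plus fresh Gaussian noise, so they carry the same class
#' signal through a genuinely redundant channel. All remaining genes are
#' class-independent standard noise. Label counts match `class_balance`
#' within one sample. One root seed streams to the label draw, the
#' informative draw and the noise draw in that fixed order.
#'
#' @param spec A [synthetic_spec()].
#' @return `list(dataset = expression_dataset, truth = list(
#'   informative_indices, redundant_map))`, where `redundant_map` maps each
#'   redundant gene index to its informative parent index.
#' @examples
#' out <- generate_expression(synthetic_spec(40, 30, n_informative = 3,
#'                                           seed = 1))
#' out$truth$informative_indices
#' @export
generate_expression <- function(spec) {
  if (!inherits(spec, "synthetic_spec"))
    stop("`spec` must be a synthetic_spec", call. = FALSE)
  n <- spec$n_samples; g <- spec$n_genes
  n_pos <- round(spec$class_balance * n)
  n_pos <- max(2L, min(n - 2L, n_pos))  # both classes usable downstream

  labels <- with_seed(derive_seed(spec$seed, "labels"), {
    sample(rep(c("tumour", "normal"), c(n_pos, n - n_pos)))
  })
  pos <- labels == "tumour"

  inf_idx <- seq_len(spec$n_informative)
  red_idx <- seq_len(spec$n_redundant) + spec$n_informative
  m <- matrix(0, n, g)

  with_seed(derive_seed(spec$seed, "informative"), {
    for (j in inf_idx) {
      shift <- spec$effect_size * spec$noise_sd
      m[, j] <- stats::rnorm(n, mean = ifelse(pos, shift, 0),
                             sd = spec$noise_sd)
    }
  })

  redundant_map <- integer(0)
  if (spec$n_redundant > 0) {
    redundant_map <- with_seed(derive_seed(spec$seed, "redundant"), {
      parents <- sample(inf_idx, spec$n_redundant, replace = TRUE)
      for (i in seq_along(red_idx))
        m[, red_idx[i]] <- m[, parents[i]] +
          stats::rnorm(n, sd = spec$redundant_noise_sd)
      stats::setNames(parents, red_idx)
    })
  }

  with_seed(derive_seed(spec$seed, "noise"), {
    rest <- setdiff(seq_len(g), c(inf_idx, red_idx))
    if (length(rest))
      m[, rest] <- stats::rnorm(n * length(rest), sd = spec$noise_sd)
  })

  ds <- expression_dataset(m, paste0("gene_", seq_len(g)), labels,
                           positive = "tumour", provenance = "synthetic")
  list(dataset = ds,
       truth = list(informative_indices = inf_idx,
                    redundant_map = redundant_map))
}

#' Generate a colon-microarray-like benchmark dataset
#'
#' A 62-sample x 2000-gene dataset with a 40/22 tumour/normal split, shaped
#' like the classic two-class colon tumour microarray benchmark: 20 planted
#' informative genes, 40 redundant copies, effect size d = 2.
#'
#' @param seed Integer seed.
#' @return Same structure as [generate_expression()].
#' @export
kentridge_like <- function(seed = 0L) {
  generate_expression(synthetic_spec(
    n_samples = 62L, n_genes = 2000L, n_informative = 20L, n_redundant = 40L,
    effect_size = 2, class_balance = 40 / 62, noise_sd = 1, seed = seed))
}

#' Write a synthetic dataset to plain files
#'
#' Writes the expression matrix as CSV (samples in rows, `sample` id column),
#' the labels as a two-column CSV, and the ground truth as JSON.
#'
#' @param out Output of [generate_expression()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the three file paths.
#' @export
write_synthetic <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- out$dataset
  expr_path <- file.path(dir, "expression.csv")
  df <- data.frame(sample = paste0("s", seq_len(nrow(ds$matrix))),
                   ds$matrix, check.names = FALSE)
  utils::write.table(df, expr_path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  label_path <- file.path(dir, "labels.csv")
  utils::write.table(
    data.frame(sample = df$sample, label = as.character(ds$labels)),
    label_path, sep = ",", row.names = FALSE, quote = FALSE)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(informative_indices = out$truth$informative_indices,
         redundant_map = as.list(out$truth$redundant_map)),
    truth_path, auto_unbox = FALSE)
  invisible(c(expression = expr_path, labels = label_path,
              truth = truth_path))
}
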