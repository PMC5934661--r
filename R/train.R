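#' Train an integrative scoring model
#'
#' Learns everything needed to score query variants, from a training table of
#' per-variant scores (missing values allowed):
#'
#' 1. *Transform*: systems reporting p-values are `-log2`-transformed
#'    ([apply_transforms()]).
#' 2. *Standardize*: each system is rescaled to mean 0, variance 1 over its
#'    observed values; the original/rescaled extremes are retained for query
#'    rescaling ([standardize_training()]).
#' 3. *Correlate*: the systems' pairwise-complete correlation matrix
#'    ([pairwise_correlation()]).
#' 4. *Weight*: the lead eigenvector of that matrix ([estimate_weights()]).
#'
#' Training IW-scores are then computed on the imputation-completed
#' standardized matrix ([multiple_impute()]) and the null distribution fitted
#' to them ([fit_null()]). A complete-case reference pool of up to
#' `reference_size` standardized rows is sampled (with `seed`) for the
#' query-imputation merge.
#'
#' @param scores Training score tibble: optional key columns
#'   `chrom, pos, ref, alt`, then one numeric column per system.
#' @param workflow Preset (`"K11"`, `"K10"`, `"N8"`, `"N6"`) selecting the
#'   active systems; ignored when `systems` is given. Each workflow retrains
#'   its own weights and null on its subset.
#' @param systems Optional custom character vector of system columns.
#' @param seed Integer seed for the reference-pool sample and imputation.
#' @param transformed Set `TRUE` when the input is already on the analysis
#'   scale (e.g. simulated scores), skipping step 1.
#' @param null_family Null family passed to [fit_null()].
#' @param imputation An [imputation_config()]; its seed is derived from
#'   `seed` unless supplied explicitly.
#' @param reference_size Reference-pool cap (default 100 000).
#' @param p_floor Floor for the p-value transform.
#' @return An `iw_model`: list with `workflow`, `systems` (spec tibble),
#'   `rescale`, `weights`, `lead_eigenvalue`, `null`, `reference_pool`
#'   (standardized complete-case matrix), `n_train`, `seed`,
#'   `transformed_input`, `imputation`, `p_floor`.
#' @seealso [score_variants()], [save_iw_model()], [tidy.iw_model()]
#' @export
iw_train <- function(scores, workflow = "K11", systems = NULL, seed = 1,
                     transformed = FALSE,
                     null_family = c("shifted_lognormal", "empirical"),
                     imputation = NULL, reference_size = 100000,
                     p_floor = 1e-16) {
  null_family <- match.arg(null_family)
  specs <- system_specs(workflow, systems)
  if (!is.null(systems)) workflow <- "custom"
  absent <- setdiff(specs$system, names(scores))
  if (length(absent) > 0) {
    abort(sprintf("training table lacks system(s): %s",
                  paste(absent, collapse = ", ")))
  }
  imputation <- imputation %||% imputation_config(seed = seed + 1L)

  work <- scores[specs$system]
  if (!transformed) work <- apply_transforms(work, specs, p_floor = p_floor)
  std <- standardize_training(work, specs$system)
  corr <- pairwise_correlation(std$scores, specs$system)
  weights <- estimate_weights(corr)

  z <- score_matrix(std$scores, specs$system)
  completed <- multiple_impute(z, imputation)$scores
  train_iw <- as.numeric(completed %*% as.numeric(weights))
  null <- fit_null(train_iw, family = null_family)

  complete_rows <- which(complete.cases(z))
  n_pool <- min(length(complete_rows), reference_size)
  pool_rows <- if (n_pool > 0) {
    withr::with_seed(seed, sort(sample(complete_rows, n_pool)))
  } else {
    integer()
  }
  if (n_pool == 0) {
    warn("no complete-case training rows: reference pool is empty")
  }
  pool <- z[pool_rows, , drop = FALSE]

  structure(
    list(
      workflow = workflow,
      systems = specs,
      rescale = std$rescale,
      weights = setNames(as.numeric(weights), names(weights)),
      lead_eigenvalue = attr(weights, "lead_eigenvalue"),
      null = null,
      reference_pool = pool,
      n_train = nrow(scores),
      seed = as.integer(seed),
      transformed_input = transformed,
      imputation = unclass(imputation)[c("n_imputations", "seed",
                                         "reference_size", "max_em_iters",
                                         "em_tol", "ridge")],
      p_floor = p_floor
    ),
    class = "iw_model"
  )
}

#' @export
print.iw_model <- function(x, ...) {
  cat(sprintf("<iw_model> workflow %s: %d systems, trained on %d variants\n",
              x$workflow, nrow(x$systems), x$n_train))
  w <- sort(x$weights, decreasing = TRUE)
  cat("  weights:", paste(sprintf("%s=%.3f", names(w), w), collapse = ", "), "\n")
  cat(sprintf("  lead eigenvalue %.3f; null %s (train mean %.3f, sd %.3f)\n",
              x$lead_eigenvalue, x$null$family,
              x$null$train_mean, x$null$train_sd))
  cat(sprintf("  reference pool: %d complete rows\n", nrow(x$reference_pool)))
  invisible(x)
}
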