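#' Weighted-sum integrative score
#'
#' The IW-score of a variant is the dot product of its rescaled per-system
#' values with the system weights: `sum_i W_i * x_i`.
#'
#' @param x Numeric vector (or matrix, variants in rows) of rescaled values,
#'   one column per active system; no missing values (imputation must already
#'   have been applied).
#' @param weights Numeric weight vector of the same length/width.
#' @return Numeric score (vector for matrix input).
#' @export
#' @examples
#' iw_score(c(1, 1), c(0.6, 0.8))
iw_score <- function(x, weights) {
  if (anyNA(x)) {
    abort("missing rescaled values: run imputation before scoring")
  }
  w <- as.numeric(weights)
  if (is.matrix(x)) {
    stopifnot(ncol(x) == length(w))
    as.numeric(x %*% w)
  } else {
    stopifnot(length(x) == length(w))
    sum(w * x)
  }
}

#' Score query variants with a trained model
#'
#' The full query pipeline: transform raw system values, rescale them onto the
#' standardized training scale ([rescale_query()]; values beyond the training
#' extremes extrapolate linearly, with a warning counting such cells), impute
#' remaining missing cells against the model's reference pool
#' ([impute_query()]), form the weighted-sum IW-score, attach the upper-tail
#' p-value under the training null, and rank (descending score; ties broken
#' by `(chrom, pos, ref, alt)` lexicographic order).
#'
#' @param scores Query tibble: key columns `chrom, pos, ref, alt` plus one
#'   column per active system (missing cells allowed, but each active system
#'   column must exist).
#' @param model An `iw_model` from [iw_train()].
#' @param alpha Significance level for the `significant` flag
#'   (default 0.05, strict `p < alpha`).
#' @param seed Seed for the imputation stream (default: the model's).
#' @param transformed Whether the query is already on the analysis scale;
#'   defaults to how the model was trained.
#' @return A tibble of class `iw_scores`: `chrom, pos, ref, alt`, one
#'   rescaled column per system, `imputed_systems` (semicolon-joined ids,
#'   `""` when fully observed), `iw_score`, `p_value`, `rank`, `significant`.
#'   Row order follows the input.
#' @export
score_variants <- function(scores, model, alpha = 0.05, seed = NULL,
                           transformed = NULL) {
  stopifnot(inherits(model, "iw_model"))
  transformed <- transformed %||% model$transformed_input
  seed <- seed %||% model$seed
  specs <- model$systems
  scores <- tibble::as_tibble(scores)
  missing_keys <- setdiff(KEY_COLS, names(scores))
  if (length(missing_keys) > 0) {
    abort(sprintf("query lacks key column(s): %s",
                  paste(missing_keys, collapse = ", ")))
  }
  absent <- setdiff(specs$system, names(scores))
  if (length(absent) > 0) {
    hint <- if (any(specs$known_only[specs$system %in% absent])) {
      " (GWAVA systems only score known variants; use an N8/N6 workflow model for novel variants)"
    } else ""
    abort(sprintf("query lacks required system column(s): %s%s",
                  paste(absent, collapse = ", "), hint))
  }
  all_missing <- specs$system[colSums(!is.na(scores[specs$system])) == 0]
  if (nrow(scores) > 0 && length(all_missing) > 0) {
    hint <- if (any(specs$known_only[specs$system %in% all_missing])) {
      " (GWAVA systems only score known variants; use an N8/N6 workflow model for novel variants)"
    } else ""
    abort(sprintf("system(s) entirely unscored in the query: %s%s",
                  paste(all_missing, collapse = ", "), hint))
  }

  work <- scores[specs$system]
  if (!transformed) work <- apply_transforms(work, specs, p_floor = model$p_floor)
  res <- rescale_scores(work, model$rescale)
  if (res$n_extrapolated > 0) {
    warn(sprintf("%d query cell(s) outside the training range were linearly extrapolated",
                 res$n_extrapolated))
  }
  z <- score_matrix(res$scores, specs$system)
  mask <- is.na(z)
  if (any(mask)) {
    cfg <- imputation_config(
      n_imputations = model$imputation$n_imputations %||% 10,
      seed = seed,
      max_em_iters = model$imputation$max_em_iters %||% 5000,
      em_tol = model$imputation$em_tol %||% 1e-4,
      ridge = model$imputation$ridge
    )
    # canonical key order so the imputation stream (bootstrap + noise) does
    # not depend on how the caller happened to order the rows
    key_ord <- order(scores$chrom, scores$pos, scores$ref, scores$alt)
    z_imp <- impute_query(z[key_ord, , drop = FALSE], model$reference_pool, cfg)
    z[key_ord, ] <- z_imp
  }

  score <- iw_score(z, model$weights)
  p <- null_pvalue(model$null, score)
  ord <- order(-score, scores$chrom, scores$pos, scores$ref, scores$alt)
  rank <- integer(length(ord))
  rank[ord] <- seq_along(ord)

  out <- tibble::as_tibble(scores[KEY_COLS])
  for (i in seq_len(nrow(specs))) out[[specs$system[i]]] <- z[, i]
  out$imputed_systems <- apply(mask, 1, function(b) {
    paste(specs$system[b], collapse = ";")
  })
  out$iw_score <- score
  out$p_value <- p
  out$rank <- rank
  out$significant <- p < alpha
  class(out) <- c("iw_scores", class(out))
  out
}

#' Local-background significance of one variant's score
#'
#' Compares a target variant's IW-score to the scores of nearby known
#' variants: `z = (s - mean(background)) / sd(background)`, with the
#' upper-tail standard-normal p-value. Useful when asking whether one variant
#' stands out from its genomic neighbourhood rather than from the genome-wide
#' training null.
#'
#' @param score The target variant's IW-score (scalar).
#' @param background Numeric vector of nearby variants' IW-scores
#'   (>= 3 values, nonzero variance).
#' @return Tibble with `z` and `p_value`.
#' @export
local_significance <- function(score, background) {
  background <- background[!is.na(background)]
  if (length(background) < 3) {
    abort("local background needs at least 3 scores")
  }
  s <- sd(background)
  if (s == 0) abort("local background has zero variance")
  z <- (score - mean(background)) / s
  tibble::tibble(z = z, p_value = pnorm(z, lower.tail = FALSE))
}

#' Filter scored variants to the significant subset
#'
#' Strict threshold: keeps variants with `p_value < alpha`; input order is
#' preserved.
#'
#' @param scored Result of [score_variants()] (any data frame with a
#'   `p_value` column).
#' @param alpha Significance level (default 0.05).
#' @return The filtered tibble.
#' @export
significant_variants <- function(scored, alpha = 0.05) {
  dplyr::filter(scored, .data$p_value < alpha)
}
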