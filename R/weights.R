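#' Pairwise-complete correlation matrix of the scoring systems
#'
#' The "covariance" feeding the weight estimation is the Pearson correlation
#' between every pair of systems computed over the variants where both are
#' observed. Pairwise completion lets every observed value contribute even
#' when the same variant is missing other systems' scores. On standardized
#' columns this matrix is the covariance of the systems.
#'
#' @param scores Score tibble (standardized or raw; correlation is
#'   scale-invariant).
#' @param systems System columns to use (default: all non-key columns).
#' @param min_joint Minimum number of jointly observed variants required for
#'   each pair (default 3).
#' @return Symmetric correlation matrix with unit diagonal, dimnames =
#'   systems.
#' @export
pairwise_correlation <- function(scores, systems = NULL, min_joint = 3L) {
  if (is.null(systems)) systems <- setdiff(names(scores), KEY_COLS)
  m <- score_matrix(scores, systems)
  obs <- !is.na(m)
  joint <- crossprod(obs)
  off <- which(joint < min_joint & upper.tri(joint), arr.ind = TRUE)
  if (nrow(off) > 0) {
    pair <- sprintf("%s/%s", systems[off[1, 1]], systems[off[1, 2]])
    abort(sprintf(
      "system pair %s has only %d jointly observed variants (need >= %d)",
      pair, joint[off[1, , drop = FALSE]], min_joint))
  }
  cc <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  if (anyNA(cc)) {
    abort("pairwise correlation undefined for some pair (constant on the joint rows?)")
  }
  diag(cc) <- 1
  cc <- (cc + t(cc)) / 2
  dimnames(cc) <- list(systems, systems)
  cc
}

#' System weights from the lead eigenvector
#'
#' The weight of each scoring system is its component in the lead eigenvector
#' (the one with the greatest eigenvalue) of the systems' correlation matrix.
#' The eigenvector is unit Euclidean norm; its sign is fixed so the component
#' sum is positive. Under the assumption that the systems are conditionally
#' independent measurements of a shared latent functional state, the lead
#' eigenvector up-weights the systems that carry the most shared signal.
#'
#' @param corr Symmetric correlation (or covariance) matrix.
#' @param tol_asym Maximum tolerated asymmetry (default `1e-8`).
#' @param tol_tie Minimum gap between the two largest eigenvalues; a tie makes
#'   the lead eigenvector ill-defined and is a hard error (perturb the input
#'   if this is intentional).
#' @return Named numeric weight vector (unit norm) with attribute
#'   `lead_eigenvalue`.
#' @export
#' @examples
#' estimate_weights(matrix(c(1, 0.8, 0.8, 1), 2, 2,
#'   dimnames = list(c("a", "b"), c("a", "b"))))
estimate_weights <- function(corr, tol_asym = 1e-8, tol_tie = 1e-12) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr)) {
    abort("weight estimation needs a square matrix")
  }
  if (!all(is.finite(corr))) abort("non-finite entries in correlation matrix")
  if (max(abs(corr - t(corr))) > tol_asym) {
    abort("correlation matrix is not symmetric")
  }
  e <- eigen((corr + t(corr)) / 2, symmetric = TRUE)
  if (nrow(corr) > 1 && (e$values[1] - e$values[2]) < tol_tie) {
    abort(paste(
      "lead eigenvalue is tied: the lead eigenvector is not unique;",
      "perturb the input or drop a redundant system"))
  }
  w <- e$vectors[, 1]
  if (sum(w) < 0) w <- -w
  names(w) <- colnames(corr)
  attr(w, "lead_eigenvalue") <- e$values[1]
  w
}

#' Subsampling diagnostic for weight stability
#'
#' Re-estimates the weights on random row subsets (without replacement) of the
#' training table at the given fractions, and reports for each repeat the
#' maximum absolute per-system deviation from the full-data weights. Small
#' deviations indicate the weights are not sensitive to the training set.
#'
#' @param scores Training score tibble (post-transform).
#' @param systems System columns (default: all non-key columns).
#' @param fractions Subsample fractions in `(0, 1]`
#'   (default `c(0.2, 0.4, 0.6, 0.8)`).
#' @param n_repeats Repeats per fraction (default 5).
#' @param seed Integer seed driving all subsampling.
#' @return Tibble with one row per (fraction, repeat): `fraction`, `rep`,
#'   `ok` (FALSE when the subsample violated the correlation preconditions),
#'   `max_abs_dev`, and one deviation column `dev_<system>` per system.
#' @export
weight_stability <- function(scores, systems = NULL,
                             fractions = c(0.2, 0.4, 0.6, 0.8),
                             n_repeats = 5, seed = 1) {
  if (any(fractions <= 0 | fractions > 1)) {
    abort("fractions must lie in (0, 1]")
  }
  if (is.null(systems)) systems <- setdiff(names(scores), KEY_COLS)
  w_full <- estimate_weights(pairwise_correlation(scores, systems))
  n <- nrow(scores)
  grid <- tidyr::expand_grid(fraction = fractions, rep = seq_len(n_repeats))
  rows <- withr::with_seed(seed, purrr::pmap(grid, function(fraction, rep) {
    idx <- if (fraction == 1) seq_len(n) else sample.int(n, round(fraction * n))
    res <- tryCatch(
      estimate_weights(pairwise_correlation(scores[idx, , drop = FALSE], systems)),
      error = function(e) NULL
    )
    if (is.null(res)) {
      dev <- rep(NA_real_, length(systems))
    } else {
      dev <- abs(as.numeric(res) - as.numeric(w_full))
    }
    out <- tibble::tibble(
      fraction = fraction, rep = rep, ok = !is.null(res),
      max_abs_dev = if (is.null(res)) NA_real_ else max(dev)
    )
    out[paste0("dev_", systems)] <- as.list(dev)
    out
  }))
  dplyr::bind_rows(rows)
}
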