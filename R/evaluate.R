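check_labeled <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.integer(labels[keep])
  if (!all(labels %in% c(0L, 1L))) abort("labels must be 0/1")
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0) {
    abort("both classes must be nonempty")
  }
  list(scores = scores, labels = labels)
}

auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores) # midranks: ties count 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the ROC curve
#'
#' AUC of a score for separating class 1 (functional/pathogenic) from class 0
#' (control), by the rank (Mann–Whitney) formulation; tied score pairs
#' contribute 1/2.
#'
#' @param data Data frame holding the score and label columns.
#' @param score,label Tidy-selected columns: numeric score and 0/1 label.
#' @return Tibble with `auc`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' roc_auc(data.frame(s = c(0.9, 0.8, 0.1, 0.2), y = c(1, 1, 0, 0)), s, y)
roc_auc <- function(data, score, label) {
  d <- check_labeled(dplyr::pull(data, {{ score }}), dplyr::pull(data, {{ label }}))
  tibble::tibble(auc = auc_rank(d$scores, d$labels),
                 n_pos = sum(d$labels == 1), n_neg = sum(d$labels == 0))
}

#' Bootstrap confidence interval for the AUC
#'
#' Percentile bootstrap stratified by class: each resample draws the positive
#' and negative sets independently with replacement, recomputes the AUC, and
#' the CI is the 2.5/97.5 percentile of the resampled AUCs.
#'
#' @inheritParams roc_auc
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed Integer seed (same seed, same CI).
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble with `auc`, `conf_low`, `conf_high`, `n_boot`.
#' @export
auc_ci <- function(data, score, label, n_boot = 2000, seed = 1,
                   conf_level = 0.95) {
  d <- check_labeled(dplyr::pull(data, {{ score }}), dplyr::pull(data, {{ label }}))
  pos <- d$scores[d$labels == 1]
  neg <- d$scores[d$labels == 0]
  if (length(pos) < 2 || length(neg) < 2) {
    abort("bootstrap CI needs at least 2 scores per class")
  }
  boots <- withr::with_seed(seed, vapply(seq_len(n_boot), function(i) {
    bp <- pos[sample.int(length(pos), replace = TRUE)]
    bn <- neg[sample.int(length(neg), replace = TRUE)]
    auc_rank(c(bp, bn), rep(c(1L, 0L), c(length(bp), length(bn))))
  }, numeric(1)))
  q <- quantile(boots, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                names = FALSE, type = 7)
  tibble::tibble(auc = auc_rank(d$scores, d$labels),
                 conf_low = q[1], conf_high = q[2], n_boot = n_boot)
}

#' Wilcoxon rank-sum test between two score samples
#'
#' Two-sided Mann–Whitney/Wilcoxon rank-sum comparison, e.g. of functional
#' scores between pathogenic and benign variants. The p-value is exact (by
#' enumeration) when the combined sample size is at most 12 and there are no
#' ties; otherwise the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param a,b Numeric score vectors (both nonempty).
#' @return Tibble with `statistic` (the Mann–Whitney W of `a` vs `b`),
#'   `p_value` and `method` (`"exact"` or `"normal_approx"`).
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
wilcoxon_rank_sum <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) abort("both samples must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b)) <= 12 && !ties
  ht <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 method = if (exact) "exact" else "normal_approx")
}

#' Wilkinson's combined p-value
#'
#' Combines `k` p-values through the `r`-th smallest: under the global null
#' the `r`-th order statistic of `k` uniform p-values is Beta(`r`,
#' `k - r + 1`), so the combined p is that Beta CDF evaluated at the `r`-th
#' smallest p. With the default `r = 1` this is the minimum-p form
#' `1 - (1 - p_min)^k`.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param r Order statistic to combine on, `1 <= r <= length(pvals)`.
#' @return Combined p-value (scalar).
#' @export
#' @examples
#' wilkinson_combined_p(c(0.1, 0.5)) # 1 - 0.9^2 = 0.19
wilkinson_combined_p <- function(pvals, r = 1) {
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) == 0) abort("no p-values to combine")
  if (any(pvals < 0 | pvals > 1)) abort("p-values must lie in [0, 1]")
  k <- length(pvals)
  if (r < 1 || r > k) abort(sprintf("r must lie in [1, %d]", k))
  pbeta(sort(pvals)[r], r, k - r + 1)
}

#' Per-system score coverage
#'
#' Fraction of variants each system scored (observed, pre-imputation), and
#' the overall fraction of variants with at least one observed score.
#'
#' @param scores Score tibble (key columns optional).
#' @param systems System columns (default: all non-key columns).
#' @return Tibble with one row per system (`system`, `n_scored`, `fraction`)
#'   plus a final `"<any>"` row for the at-least-one coverage.
#' @export
coverage_report <- function(scores, systems = NULL) {
  if (is.null(systems)) systems <- setdiff(names(scores), KEY_COLS)
  m <- !is.na(score_matrix(scores, systems))
  n <- nrow(m)
  per <- tibble::tibble(
    system = systems,
    n_scored = unname(as.integer(colSums(m))),
    fraction = if (n == 0) rep(NA_real_, length(systems))
               else unname(colSums(m)) / n
  )
  any_row <- tibble::tibble(
    system = "<any>",
    n_scored = as.integer(sum(rowSums(m) > 0)),
    fraction = if (n == 0) NA_real_ else sum(rowSums(m) > 0) / n
  )
  dplyr::bind_rows(per, any_row)
}
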