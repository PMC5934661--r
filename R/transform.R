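#' Map raw system scores onto the integration scale
#'
#' Systems whose raw output is a p-value in `(0, 1]` (DeepSEA functional
#' significance) are transformed by `-log2(max(p, p_floor))` so that larger
#' values mean more functional, like every other system. Identity systems are
#' returned unchanged; missing values are preserved.
#'
#' @param scores Score tibble (key columns optional, one column per system).
#' @param specs System specification tibble (see [iw_systems()]); only rows
#'   whose `system` is a column of `scores` are used.
#' @param p_floor Lower bound applied before the log so that underflowing
#'   p-values map to a finite ceiling (default `1e-16`, i.e. max 53.15).
#' @return `scores` with transformed columns.
#' @export
apply_transforms <- function(scores, specs = iw_systems(), p_floor = 1e-16) {
  specs <- specs[specs$system %in% names(scores), , drop = FALSE]
  for (i in seq_len(nrow(specs))) {
    if (specs$transform[i] != "neg_log2_p") next
    s <- specs$system[i]
    x <- scores[[s]]
    obs <- !is.na(x)
    if (any(x[obs] <= 0 | x[obs] > 1)) {
      abort(sprintf(
        "system '%s' uses the -log2 p-value transform but has values outside (0, 1]", s))
    }
    x[obs] <- -log2(pmax(x[obs], p_floor))
    scores[[s]] <- x
  }
  scores
}

#' Standardize training scores and record rescale parameters
#'
#' Each system column is rescaled to mean 0, variance 1 over its observed
#' entries (sample standard deviation, `n - 1` denominator); missing entries
#' are untouched. The per-system minima/maxima of the original (`min_a`,
#' `max_a`) and rescaled (`min_r`, `max_r`) values are retained, together with
#' the mean and sd, for mapping query scores onto the training scale later
#' (see [rescale_query()]).
#'
#' @param scores Score tibble (post-transform).
#' @param systems Character vector of system columns to standardize
#'   (default: all non-key columns).
#' @return A list with `scores` (standardized tibble) and `rescale` (tibble
#'   with columns `system`, `mean`, `sd`, `min_a`, `max_a`, `min_r`, `max_r`).
#' @export
standardize_training <- function(scores, systems = NULL) {
  if (is.null(systems)) systems <- setdiff(names(scores), KEY_COLS)
  params <- vector("list", length(systems))
  for (i in seq_along(systems)) {
    s <- systems[i]
    x <- scores[[s]]
    obs <- x[!is.na(x)]
    if (length(obs) < 2) {
      abort(sprintf("system '%s' has fewer than 2 observed values", s))
    }
    mu <- mean(obs)
    sigma <- sd(obs)
    if (!is.finite(sigma) || sigma == 0) {
      abort(sprintf("zero variance: %s", s))
    }
    z <- (x - mu) / sigma
    scores[[s]] <- z
    params[[i]] <- tibble::tibble(
      system = s, mean = mu, sd = sigma,
      min_a = min(obs), max_a = max(obs),
      min_r = min(z, na.rm = TRUE), max_r = max(z, na.rm = TRUE)
    )
  }
  list(scores = scores, rescale = dplyr::bind_rows(params))
}

#' Rescale a query score onto the training scale
#'
#' Maps a raw query value `m` for system `i` onto the standardized training
#' scale by the linear interpolation anchored at the training extremes:
#' \deqn{x = \frac{Max_R (m - Min_A) + Min_R (Max_A - m)}{Max_A - Min_A}}
#' so `m = Min_A` maps exactly to `Min_R` and `m = Max_A` to `Max_R`. The map
#' is linear, so values outside the training range extrapolate; because the
#' training rescaling is a z-transform, this is algebraically identical to
#' `(m - mean)/sd` with the training moments.
#'
#' @param m Numeric vector of raw query values (`NA` passed through).
#' @param params A single-system row of the `rescale` tibble from
#'   [standardize_training()] (fields `min_a`, `max_a`, `min_r`, `max_r`).
#' @return Numeric vector of rescaled values.
#' @export
rescale_query <- function(m, params) {
  if (!(params$max_a > params$min_a)) {
    abort(sprintf("degenerate rescale parameters for '%s': max_a must exceed min_a",
                  params$system %||% "<system>"))
  }
  x <- (params$max_r * (m - params$min_a) + params$min_r * (params$max_a - m)) /
    (params$max_a - params$min_a)
  # pin the anchors: the interpolation formula can be 1 ulp off at the
  # training extremes, which must map to the stored endpoints exactly
  x[which(m == params$min_a)] <- params$min_r
  x[which(m == params$max_a)] <- params$max_r
  x
}

## apply rescale_query column-wise; returns list(scores, n_extrapolated)
rescale_scores <- function(scores, rescale) {
  n_extra <- 0L
  for (i in seq_len(nrow(rescale))) {
    s <- rescale$system[i]
    if (!s %in% names(scores)) next
    x <- scores[[s]]
    obs <- !is.na(x)
    n_extra <- n_extra +
      sum(x[obs] < rescale$min_a[i] | x[obs] > rescale$max_a[i])
    scores[[s]] <- rescale_query(x, rescale[i, ])
  }
  list(scores = scores, n_extrapolated = n_extra)
}
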