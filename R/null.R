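#' Fit the null distribution of training IW-scores
#'
#' Integrative scores over a large unlabeled training set are strongly
#' right-skewed and approximately lognormal, but have negative support, so a
#' *shifted* lognormal is fitted: with `shift = -min(scores) + eps`
#' (`eps = 1e-6 *` score range), `log(score + shift)` is fitted by maximum
#' likelihood (`meanlog`, `sdlog`). The full sorted score vector is retained
#' so an empirical-quantile null can be selected instead; the plain training
#' mean and SD are recorded for reporting.
#'
#' @param scores Numeric vector of training IW-scores (>= 100 values,
#'   nonzero variance).
#' @param family `"shifted_lognormal"` (default) or `"empirical"`.
#' @return An `iw_null` object with fields `family`, `shift`, `meanlog`,
#'   `sdlog`, `train_mean`, `train_sd`, `sorted_scores`.
#' @export
fit_null <- function(scores, family = c("shifted_lognormal", "empirical")) {
  family <- match.arg(family)
  scores <- scores[!is.na(scores)]
  if (length(scores) < 100) {
    abort("null fit needs at least 100 training scores")
  }
  rng <- range(scores)
  if (rng[1] == rng[2]) abort("training scores are constant; null undefined")
  shift <- -rng[1] + 1e-6 * diff(rng)
  lx <- log(scores + shift)
  meanlog <- mean(lx)
  sdlog <- sqrt(mean((lx - meanlog)^2)) # MLE (n denominator)
  structure(
    list(
      family = family, shift = shift, meanlog = meanlog, sdlog = sdlog,
      train_mean = mean(scores), train_sd = sd(scores),
      sorted_scores = sort(scores)
    ),
    class = "iw_null"
  )
}

#' Upper-tail p-value of an IW-score under the fitted null
#'
#' Under the shifted lognormal, `p = 1 - CDF(score + shift)`; scores at or
#' below the fitted support get `p = 1`. Under the empirical family,
#' `p = (r + 1) / (N + 1)` where `r` is the number of training scores `>=`
#' the query score, so a score above the whole training set gets
#' `1 / (N + 1)`. p-values are clamped into `(0, 1]` and are monotonically
#' non-increasing in the score.
#'
#' @param null An `iw_null` from [fit_null()].
#' @param score Numeric vector of IW-scores.
#' @return Numeric vector of p-values in `(0, 1]`.
#' @export
null_pvalue <- function(null, score) {
  stopifnot(inherits(null, "iw_null"))
  if (null$family == "shifted_lognormal") {
    y <- score + null$shift
    p <- rep(1, length(score))
    pos <- which(y > 0)
    p[pos] <- plnorm(y[pos], null$meanlog, null$sdlog, lower.tail = FALSE)
    pmin(pmax(p, .Machine$double.xmin), 1)
  } else {
    s <- null$sorted_scores
    n <- length(s)
    n_lt <- findInterval(score, s, left.open = TRUE)
    ((n - n_lt) + 1) / (n + 1)
  }
}

#' @export
print.iw_null <- function(x, ...) {
  cat(sprintf(
    "<iw_null> %s over %d training scores (mean %.3f, sd %.3f)\n",
    x$family, length(x$sorted_scores), x$train_mean, x$train_sd))
  if (x$family == "shifted_lognormal") {
    cat(sprintf("  shift %.4g, meanlog %.4f, sdlog %.4f\n",
                x$shift, x$meanlog, x$sdlog))
  }
  invisible(x)
}
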