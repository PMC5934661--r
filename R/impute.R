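#' Imputation configuration
#'
#' Settings for the expectation-maximization-with-bootstrap (EMB) multiple
#' imputation of missing scores.
#'
#' @param n_imputations Number of completed datasets averaged into the final
#'   imputed value (default 10).
#' @param seed Integer seed driving bootstrap resampling and the
#'   conditional-variance noise.
#' @param reference_size Maximum number of complete-case training rows kept as
#'   the reference pool merged into small query sets (default 100 000, capped
#'   at the number of complete cases available).
#' @param max_em_iters Maximum EM iterations (default 5000; small
#'   ill-conditioned bootstrap samples can converge slowly).
#' @param em_tol Convergence threshold on the maximum absolute parameter
#'   change (default 1e-4, the customary tolerance for EM-based imputation;
#'   tighter values slow convergence markedly on small resamples).
#' @param ridge Diagonal regularizer added to the covariance after each
#'   M-step. `NULL` (default) uses `1e-6 * trace/k`, guarding the
#'   near-singular covariances bootstrap samples of strongly correlated
#'   scores often produce.
#' @return A list of class `iw_imputation_config`.
#' @export
imputation_config <- function(n_imputations = 10, seed = 1,
                              reference_size = 100000,
                              max_em_iters = 5000, em_tol = 1e-4,
                              ridge = NULL) {
  stopifnot(n_imputations >= 1, em_tol > 0, is.null(ridge) || ridge >= 0)
  structure(
    list(n_imputations = as.integer(n_imputations), seed = as.integer(seed),
         reference_size = as.integer(reference_size),
         max_em_iters = as.integer(max_em_iters), em_tol = em_tol,
         ridge = ridge),
    class = "iw_imputation_config"
  )
}

check_identifiable <- function(x) {
  obs <- !is.na(x)
  n_obs <- colSums(obs)
  if (any(n_obs < 2)) {
    abort(sprintf("column '%s' has fewer than 2 observed values",
                  colnames(x)[which(n_obs < 2)[1]]))
  }
  joint <- crossprod(obs)
  bad <- which(joint == 0 & upper.tri(joint), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "columns '%s' and '%s' are never jointly observed: model not identifiable",
      colnames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]))
  }
  invisible(x)
}

## rows grouped by missingness pattern; returns list of (rows, obs, mis)
missingness_patterns <- function(miss) {
  key <- apply(miss, 1, function(b) paste(as.integer(b), collapse = ""))
  lapply(split(seq_len(nrow(miss)), key), function(rows) {
    b <- miss[rows[1], ]
    list(rows = rows, obs = which(!b), mis = which(b))
  })
}

#' Fit a multivariate normal by EM under ignorable missingness
#'
#' Maximum-likelihood mean and covariance of a multivariate normal from data
#' with missing entries (assumed missing at random), by
#' expectation-maximization over the row missingness patterns. The covariance
#' uses the maximum-likelihood (`n`) denominator and is regularized by
#' `ridge * I` after each M-step.
#'
#' @param x Numeric matrix (rows = observations) with `NA` for missing.
#' @param config An [imputation_config()].
#' @return List with `mu` (named mean vector), `sigma` (covariance matrix),
#'   `iterations` and `delta` (last parameter change).
#' @export
em_fit <- function(x, config = imputation_config()) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  k <- ncol(x)
  n <- nrow(x)
  check_identifiable(x)
  miss <- is.na(x)
  mu <- colMeans(x, na.rm = TRUE)
  v <- apply(x, 2, var, na.rm = TRUE)
  v[!is.finite(v) | v == 0] <- 1
  sigma <- diag(v, k)
  ridge <- config$ridge %||% (1e-6 * mean(v))
  if (!any(miss)) {
    xc <- sweep(x, 2, mu)
    sigma <- crossprod(xc) / n + diag(ridge, k)
    dimnames(sigma) <- list(colnames(x), colnames(x))
    return(list(mu = mu, sigma = sigma, iterations = 1L, delta = 0))
  }
  pats <- missingness_patterns(miss)
  delta <- Inf
  for (iter in seq_len(config$max_em_iters)) {
    s1 <- numeric(k)
    s2 <- matrix(0, k, k)
    for (p in pats) {
      rows <- p$rows
      o <- p$obs
      m <- p$mis
      xc <- matrix(0, length(rows), k)
      if (length(o) > 0) xc[, o] <- x[rows, o, drop = FALSE]
      if (length(m) > 0) {
        if (length(o) == 0) {
          xc[, m] <- matrix(mu[m], length(rows), length(m), byrow = TRUE)
          cc <- sigma[m, m, drop = FALSE]
        } else {
          b <- solve(sigma[o, o, drop = FALSE], sigma[o, m, drop = FALSE])
          xc[, m] <- matrix(mu[m], length(rows), length(m), byrow = TRUE) +
            sweep(x[rows, o, drop = FALSE], 2, mu[o]) %*% b
          cc <- sigma[m, m, drop = FALSE] -
            crossprod(sigma[o, m, drop = FALSE], b)
        }
        s2[m, m] <- s2[m, m] + length(rows) * cc
      }
      s1 <- s1 + colSums(xc)
      s2 <- s2 + crossprod(xc)
    }
    mu_new <- s1 / n
    sigma_new <- s2 / n - tcrossprod(mu_new)
    sigma_new <- (sigma_new + t(sigma_new)) / 2 + diag(ridge, k)
    delta <- max(max(abs(mu_new - mu)), max(abs(sigma_new - sigma)))
    mu <- mu_new
    sigma <- sigma_new
    if (delta < config$em_tol) break
  }
  if (delta >= config$em_tol) {
    abort(sprintf("EM did not converge after %d iterations (last delta %.3g)",
                  config$max_em_iters, delta))
  }
  names(mu) <- colnames(x)
  dimnames(sigma) <- list(colnames(x), colnames(x))
  list(mu = mu, sigma = sigma, iterations = iter, delta = delta)
}

## complete x under fit; noise adds a draw from the conditional covariance.
## assumes the RNG stream is already seeded by the caller.
draw_completion <- function(x, fit, noise = TRUE) {
  miss <- is.na(x)
  if (!any(miss)) return(x)
  for (p in missingness_patterns(miss)) {
    m <- p$mis
    if (length(m) == 0) next
    rows <- p$rows
    o <- p$obs
    if (length(o) == 0) {
      cmean <- matrix(fit$mu[m], length(rows), length(m), byrow = TRUE)
      cc <- fit$sigma[m, m, drop = FALSE]
    } else {
      b <- solve(fit$sigma[o, o, drop = FALSE], fit$sigma[o, m, drop = FALSE])
      cmean <- matrix(fit$mu[m], length(rows), length(m), byrow = TRUE) +
        sweep(x[rows, o, drop = FALSE], 2, fit$mu[o]) %*% b
      cc <- fit$sigma[m, m, drop = FALSE] -
        crossprod(fit$sigma[o, m, drop = FALSE], b)
    }
    if (noise) {
      cc <- (cc + t(cc)) / 2
      ch <- tryCatch(chol(cc), error = function(e) {
        chol(cc + diag(1e-10 * (1 + mean(diag(cc))), nrow(cc)))
      })
      cmean <- cmean + matrix(rnorm(length(rows) * length(m)),
                              length(rows), length(m)) %*% ch
    }
    x[rows, m] <- cmean
  }
  x
}

#' Multiple imputation by EM with bootstrap
#'
#' Produces `n_imputations` completed copies of the input: each copy fits the
#' multivariate-normal model by [em_fit()] on a bootstrap resample of the rows
#' (propagating parameter uncertainty between imputations), then fills every
#' missing cell with a draw from its conditional distribution given the row's
#' observed values (conditional mean plus conditional-variance noise). The
#' returned value of each missing cell is the mean over the
#' `n_imputations` draws. Observed cells are never altered.
#'
#' @param scores Score tibble (key columns optional) or numeric matrix.
#' @param config An [imputation_config()]; `config$seed` makes the result
#'   deterministic.
#' @param systems System columns to impute (default: all non-key columns).
#' @return List with `scores` (completed tibble/matrix, same shape and order
#'   as the input) and `mask` (logical matrix of imputed cells, columns =
#'   systems).
#' @export
multiple_impute <- function(scores, config = imputation_config(),
                            systems = NULL) {
  is_df <- is.data.frame(scores)
  if (is_df) {
    if (is.null(systems)) systems <- setdiff(names(scores), KEY_COLS)
    x <- score_matrix(scores, systems)
  } else {
    x <- as.matrix(scores)
    systems <- colnames(x)
  }
  mask <- is.na(x)
  if (!any(mask)) {
    return(list(scores = scores, mask = mask))
  }
  check_identifiable(x)
  n <- nrow(x)
  acc <- matrix(0, n, ncol(x))
  withr::with_seed(config$seed, {
    for (j in seq_len(config$n_imputations)) {
      idx <- sample.int(n, n, replace = TRUE)
      fit <- em_fit(x[idx, , drop = FALSE], config)
      acc <- acc + draw_completion(x, fit, noise = TRUE)
    }
  })
  completed <- x
  completed[mask] <- (acc / config$n_imputations)[mask]
  if (is_df) {
    out <- scores
    for (i in seq_along(systems)) out[[systems[i]]] <- completed[, i]
  } else {
    out <- completed
  }
  list(scores = out, mask = mask)
}

#' Impute a query set against the reference pool
#'
#' Query sets are usually far too small to estimate the between-system
#' covariance, so the query rows are stacked on a pool of complete-case
#' training rows (up to 100 000, stored in the model), multiple imputation
#' runs on the union, and only the completed query rows are returned. The
#' pool lives in the standardized training space, so the query must already
#' be rescaled onto that space.
#'
#' @param query Numeric matrix or score tibble in the standardized training
#'   space (missing allowed).
#' @param reference_pool Complete numeric matrix with the same system columns.
#' @param config An [imputation_config()].
#' @return Same shape/order as `query`, completed, plus a `mask` attribute of
#'   the imputed cells.
#' @export
impute_query <- function(query, reference_pool, config = imputation_config()) {
  is_df <- is.data.frame(query)
  systems <- if (is_df) setdiff(names(query), KEY_COLS) else colnames(query)
  x <- if (is_df) score_matrix(query, systems) else as.matrix(query)
  if (!all(systems %in% colnames(reference_pool))) {
    abort(sprintf("reference pool lacks system(s): %s",
                  paste(setdiff(systems, colnames(reference_pool)), collapse = ", ")))
  }
  mask <- is.na(x)
  if (!any(mask)) {
    attr(query, "mask") <- mask
    return(query)
  }
  pool <- reference_pool[, systems, drop = FALSE]
  stacked <- rbind(x, pool)
  res <- multiple_impute(stacked, config)
  completed <- res$scores[seq_len(nrow(x)), , drop = FALSE]
  if (is_df) {
    out <- query
    for (i in seq_along(systems)) out[[systems[i]]] <- completed[, i]
  } else {
    out <- completed
  }
  attr(out, "mask") <- mask
  out
}
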