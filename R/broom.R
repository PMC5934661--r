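#' Tidy a trained model
#'
#' One row per active scoring system: its weight and the training rescale
#' parameters.
#'
#' @param x An `iw_model`.
#' @param ... Unused.
#' @return Tibble with columns `system`, `weight`, `transform`, `mean`, `sd`,
#'   `min_a`, `max_a`, `min_r`, `max_r`.
#' @export
tidy.iw_model <- function(x, ...) {
  dplyr::left_join(
    tibble::tibble(system = names(x$weights), weight = unname(x$weights)),
    dplyr::left_join(x$systems[c("system", "transform")], x$rescale,
                     by = "system"),
    by = "system"
  )
}

#' One-row model summary
#'
#' @param x An `iw_model`.
#' @param ... Unused.
#' @return Tibble with `workflow`, `n_systems`, `n_train`, `lead_eigenvalue`,
#'   `null_family`, `null_shift`, `null_meanlog`, `null_sdlog`,
#'   `train_mean`, `train_sd`, `n_reference_pool`.
#' @export
glance.iw_model <- function(x, ...) {
  tibble::tibble(
    workflow = x$workflow,
    n_systems = nrow(x$systems),
    n_train = x$n_train,
    lead_eigenvalue = x$lead_eigenvalue,
    null_family = x$null$family,
    null_shift = x$null$shift,
    null_meanlog = x$null$meanlog,
    null_sdlog = x$null$sdlog,
    train_mean = x$null$train_mean,
    train_sd = x$null$train_sd,
    n_reference_pool = nrow(x$reference_pool)
  )
}

#' Plot the system weights of a trained model
#'
#' @param object An `iw_model`.
#' @param ... Unused.
#' @return A ggplot: systems ordered by weight.
#' @export
autoplot.iw_model <- function(object, ...) {
  d <- tidy.iw_model(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$system, .data$weight), y = .data$weight
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "lead-eigenvector weight",
      title = sprintf("System weights (workflow %s)", object$workflow)
    ) +
    ggplot2::theme_minimal()
}

#' Plot scored variants along the genome
#'
#' IW-score against genomic position, one panel per chromosome, with
#' significant variants highlighted — the view used to spot runs of
#' functional mutations.
#'
#' @param object An `iw_scores` tibble from [score_variants()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.iw_scores <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$pos, y = .data$iw_score, colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
      name = "p < alpha"
    ) +
    ggplot2::labs(x = "position (bp)", y = "IW-score") +
    ggplot2::theme_minimal()
}

#' Plot the fitted null against the training scores
#'
#' Histogram of training IW-scores with the fitted shifted-lognormal density
#' overlaid — the visual check that the null family describes the training
#' distribution.
#'
#' @param model An `iw_model`.
#' @return A ggplot.
#' @export
plot_null <- function(model) {
  stopifnot(inherits(model, "iw_model"))
  null <- model$null
  d <- tibble::tibble(score = null$sorted_scores)
  grid <- seq(min(d$score), max(d$score), length.out = 400)
  dens <- stats::dlnorm(grid + null$shift, null$meanlog, null$sdlog)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 60, fill = "grey80", colour = "grey50") +
    ggplot2::geom_line(
      data = tibble::tibble(score = grid, density = dens),
      ggplot2::aes(y = .data$density), colour = "firebrick"
    ) +
    ggplot2::labs(x = "training IW-score", y = "density",
                  title = "Training score distribution and fitted null") +
    ggplot2::theme_minimal()
}
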