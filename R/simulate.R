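#' Simulation configuration for synthetic score matrices
#'
#' Defines the generative model used throughout the package's tests and
#' examples: a latent two-class functional signal measured by correlated
#' scoring systems. A variant is functional with probability `prevalence`;
#' its latent signal is `s ~ N(delta * label, 1)`; system `i` emits
#' `loadings[i] * s` plus Gaussian residual noise whose correlation has a
#' block structure (one tight block of five systems mimicking the closely
#' correlated ensemble members, one moderate block of the three
#' known-variant-only classifiers, the rest independent). Cells are then
#' masked missing completely at random (MCAR) at per-system rates; an
#' optional MAR mode makes system 2's missingness depend on system 1's value
#' for stress tests.
#'
#' @param systems Character vector of system names (default: the 11-system
#'   registry).
#' @param loadings Named or positional numeric vector of per-system signal
#'   loadings.
#' @param blocks List of integer vectors: residual-correlation block
#'   memberships (indices into `systems`).
#' @param block_rho Within-block residual correlations, one per block.
#' @param delta Latent mean shift of the functional class (default 1.5).
#' @param prevalence Probability a variant is functional (default 0.5).
#' @param missing_rates Per-system MCAR missingness rates in `[0, 1)`
#'   (default between 5% and 45%).
#' @param mar If `TRUE`, missingness of the second system depends on the
#'   first system's value (above-median values twice as likely missing).
#' @return List of class `iw_sim_config`.
#' @export
sim_config <- function(systems = iw_systems()$system,
                       loadings = NULL,
                       blocks = NULL,
                       block_rho = c(0.5, 0.3),
                       delta = 1.5,
                       prevalence = 0.5,
                       missing_rates = NULL,
                       mar = FALSE) {
  k <- length(systems)
  if (is.null(loadings)) {
    if (k != 11) abort("default loadings are defined for 11 systems; supply `loadings`")
    loadings <- c(
      cadd = 1.25, deepsea = 1.2, eigen = 1.3, eigen_pc = 0.7,
      fathmm_mkl = 1.15, fitcons = 0.5, funseq2 = 0.6,
      gwava_region = 0.8, gwava_tss = 0.85, gwava_unmatched = 0.9,
      remm = 1.1
    )[systems]
  }
  if (is.null(blocks)) {
    if (k == 11) {
      blocks <- list(
        which(systems %in% c("cadd", "deepsea", "eigen", "fathmm_mkl", "remm")),
        which(systems %in% c("gwava_region", "gwava_tss", "gwava_unmatched"))
      )
    } else {
      blocks <- list()
    }
  }
  if (is.null(missing_rates)) {
    missing_rates <- rep_len(c(0.05, 0.1, 0.15, 0.45, 0.12, 0.3, 0.25,
                               0.2, 0.35, 0.4, 0.08), k)
  }
  stopifnot(length(loadings) == k, length(missing_rates) == k,
            length(block_rho) >= length(blocks),
            prevalence > 0, prevalence < 1,
            all(missing_rates >= 0 & missing_rates < 1))
  structure(
    list(systems = systems, loadings = unname(as.numeric(loadings)),
         blocks = blocks, block_rho = block_rho, delta = delta,
         prevalence = prevalence,
         missing_rates = unname(as.numeric(missing_rates)), mar = mar),
    class = "iw_sim_config"
  )
}

residual_chol <- function(config) {
  k <- length(config$systems)
  r <- diag(k)
  for (b in seq_along(config$blocks)) {
    idx <- config$blocks[[b]]
    r[idx, idx] <- config$block_rho[b]
    diag(r)[idx] <- 1
  }
  tryCatch(chol(r), error = function(e) {
    abort("residual correlation matrix is not positive definite")
  })
}

#' Generate a two-class synthetic score matrix
#'
#' Draws `n` variants from the generative model of [sim_config()]. Uses R's
#' default Mersenne–Twister stream, fully determined by `seed`.
#'
#' @param n Number of variants.
#' @param config An [iw_sim_config][sim_config()].
#' @param seed Integer seed.
#' @param chrom Chromosome name for the generated keys (default `"chr1"`).
#' @return Tibble with key columns (`chrom`, distinct sorted `pos`, `ref`,
#'   `alt`), the ground-truth columns `label` (0/1) and `latent` (the latent
#'   signal), then one score column per system with MCAR/MAR missingness
#'   applied. Score columns are on the analysis (post-transform) scale, so
#'   train with `transformed = TRUE`.
#' @export
simulate_scores <- function(n, config = sim_config(), seed = 1,
                            chrom = "chr1") {
  ch <- residual_chol(config)
  k <- length(config$systems)
  withr::with_seed(seed, {
    pos <- sort(sample.int(max(10L * n, 1000L), n))
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt_shift <- sample.int(3L, n, replace = TRUE)
    label <- rbinom(n, 1, config$prevalence)
    latent <- rnorm(n, config$delta * label, 1)
    noise <- matrix(rnorm(n * k), n, k) %*% ch
    x <- outer(latent, config$loadings) + noise
    x_full <- x # pre-masking values drive the MAR mechanism
    for (j in seq_len(k)) {
      rate <- config$missing_rates[j]
      if (rate == 0) next
      if (config$mar && j == 2L && k >= 2L) {
        # missingness of system 2 driven by system 1's underlying value
        hi <- x_full[, 1] > median(x_full[, 1])
        pmiss <- ifelse(hi, pmin(2 * rate, 0.95), rate / 2)
        x[runif(n) < pmiss, j] <- NA
      } else {
        x[runif(n) < rate, j] <- NA
      }
    }
    bases <- c("A", "C", "G", "T")
    out <- tibble::tibble(
      chrom = chrom, pos = as.integer(pos), ref = ref,
      alt = bases[(match(ref, bases) + alt_shift - 1L) %% 4L + 1L],
      label = label, latent = latent
    )
    for (j in seq_len(k)) out[[config$systems[j]]] <- x[, j]
    out
  })
}

#' Generate a complete reference pool from the same model
#'
#' Complete-case draw (no missingness) from the generative model, standing in
#' for the complete-case training rows kept for the query-imputation merge.
#'
#' @inheritParams simulate_scores
#' @return Tibble like [simulate_scores()] but with no missing cells.
#' @export
simulate_reference_pool <- function(n, config = sim_config(), seed = 1) {
  cfg <- config
  cfg$missing_rates <- rep(0, length(config$systems))
  simulate_scores(n, cfg, seed = seed, chrom = "chrPool")
}

#' Generate genomic positions with planted clusters
#'
#' Builds a positions fixture for cluster detection: `n_clusters` groups of
#' `cluster_size` positions whose consecutive gaps are below 10 kb (members
#' drawn inside a window of `cluster_width`), planted among `n_background`
#' uniform background positions. Ground-truth membership is returned.
#'
#' @param n_background Number of uniform background positions.
#' @param n_clusters Number of planted clusters.
#' @param cluster_size Members per planted cluster (default 3).
#' @param cluster_width Width of each planted cluster's window in bp
#'   (default 5000; must be below `chrom_length / (3 * n_clusters)`).
#' @param chrom_length Chromosome length (default 1e8).
#' @param chrom Chromosome name.
#' @param seed Integer seed.
#' @return Tibble with `chrom`, `pos` (sorted, within `[1, chrom_length]`)
#'   and `cluster` (planted cluster id, 0 for background).
#' @export
simulate_positions <- function(n_background, n_clusters, cluster_size = 3,
                               cluster_width = 5000, chrom_length = 1e8,
                               chrom = "chr1", seed = 1) {
  if (n_clusters > 0 && cluster_width * 3 * n_clusters >= chrom_length) {
    abort("infeasible packing: clusters do not fit the chromosome")
  }
  withr::with_seed(seed, {
    bg <- if (n_background > 0) {
      sort(sample.int(chrom_length, n_background))
    } else integer()
    out <- tibble::tibble(chrom = chrom, pos = as.integer(bg),
                          cluster = rep(0L, length(bg)))
    if (n_clusters > 0) {
      # evenly spaced anchor slots keep planted clusters apart
      anchors <- round(seq(chrom_length * 0.1, chrom_length * 0.9,
                           length.out = n_clusters))
      for (cl in seq_len(n_clusters)) {
        offs <- sort(sample.int(cluster_width, cluster_size))
        memb <- pmin(pmax(anchors[cl] + offs, 1L), chrom_length)
        out <- dplyr::bind_rows(out, tibble::tibble(
          chrom = chrom, pos = as.integer(memb),
          cluster = rep(cl, cluster_size)
        ))
      }
    }
    dplyr::arrange(out, .data$pos)
  })
}
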