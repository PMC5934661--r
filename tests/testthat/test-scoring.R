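test_that("query rescaling interpolates and extrapolates linearly", {
  p <- tibble::tibble(system = "s", min_a = 1, max_a = 3, min_r = -1, max_r = 1)
  expect_equal(rescale_query(1, p), -1)
  expect_equal(rescale_query(2, p), 0)
  expect_equal(rescale_query(4, p), 2) # beyond max_a: linear extrapolation
  expect_true(is.na(rescale_query(NA, p)))
  bad <- tibble::tibble(system = "s", min_a = 3, max_a = 3, min_r = 0, max_r = 1)
  expect_error(rescale_query(1, bad), "max_a must exceed min_a")
})

test_that("the rescaling ratio identity holds on random draws", {
  withr::with_seed(41, {
    worst <- 0
    for (i in 1:2000) {
      min_a <- rnorm(1)
      max_a <- min_a + abs(rnorm(1)) + 0.5
      min_r <- rnorm(1)
      max_r <- min_r + abs(rnorm(1)) + 0.5
      p <- tibble::tibble(system = "s", min_a = min_a, max_a = max_a,
                          min_r = min_r, max_r = max_r)
      m <- runif(1, min_a + 0.1 * (max_a - min_a), max_a - 0.1 * (max_a - min_a))
      x <- rescale_query(m, p)
      lhs <- (max_a - m) / (m - min_a)
      rhs <- (max_r - x) / (x - min_r)
      worst <- max(worst, abs(lhs - rhs) / max(1, abs(lhs)))
    }
    expect_lt(worst, 1e-12)
  })
})

test_that("the integrative score is the weighted sum", {
  expect_equal(iw_score(c(1, 1), c(0.6, 0.8)), 1.4)
  expect_equal(iw_score(c(0, 0, 0), c(0.2, 0.3, 0.5)), 0)
  expect_equal(iw_score(c(2, -2, 1), c(0.5, 0.5, 0.70711)), 0.70711)
  expect_error(iw_score(c(1, NA), c(1, 1)), "imputation")
  # linearity
  withr::with_seed(42, {
    w <- rnorm(5)
    x <- rnorm(5)
    y <- rnorm(5)
    expect_equal(iw_score(2 * x + 3 * y, w),
                 2 * iw_score(x, w) + 3 * iw_score(y, w))
  })
})

test_that("scoring training rows reproduces their training scores", {
  cfg <- sim_config(missing_rates = rep(0, 11))
  sim <- simulate_scores(500, cfg, seed = 51)
  model <- iw_train(sim, workflow = "K11", seed = 1, transformed = TRUE)
  train_iw <- sort(model$null$sorted_scores)
  scored <- score_variants(sim[1:10, ], model)
  # each scored value must equal the training IW-score of that (complete) row
  z <- as.matrix(sim[1:10, names(model$weights)])
  for (j in seq_len(nrow(model$rescale))) {
    p <- model$rescale[j, ]
    z[, p$system] <- rescale_query(z[, p$system], p)
  }
  expect_equal(scored$iw_score, as.numeric(z %*% model$weights),
               tolerance = 1e-9)
  # and those values are present among the training null scores
  for (s in scored$iw_score) {
    expect_lt(min(abs(train_iw - s)), 1e-9)
  }
})

test_that("identical score vectors tie on score/p and split rank by coordinates", {
  sim <- simulate_scores(200, sim_config(missing_rates = rep(0, 11)), seed = 52)
  model <- iw_train(sim, workflow = "N6", seed = 1, transformed = TRUE,
                    reference_size = 100)
  q <- sim[c(5, 5), ]
  q$pos <- c(500L, 100L)
  q$chrom <- "chr9"
  scored <- score_variants(q, model)
  expect_equal(scored$iw_score[1], scored$iw_score[2])
  expect_equal(scored$p_value[1], scored$p_value[2])
  expect_equal(scored$rank[order(q$pos)], c(1L, 2L)) # lexicographic tie-break
})

test_that("scores, p-values and ranks are invariant to input row order", {
  cfg <- sim_config(missing_rates = rep(0.15, 11))
  sim <- simulate_scores(600, cfg, seed = 53)
  model <- iw_train(sim, workflow = "K11", seed = 2, transformed = TRUE,
                    reference_size = 200)
  q <- sim[1:40, ]
  s1 <- score_variants(q, model)
  perm <- withr::with_seed(1, sample(40))
  s2 <- score_variants(q[perm, ], model)
  j <- dplyr::inner_join(s1, s2, by = c("chrom", "pos", "ref", "alt"))
  expect_equal(nrow(j), 40L)
  expect_equal(j$iw_score.x, j$iw_score.y, tolerance = 1e-9)
  expect_equal(j$p_value.x, j$p_value.y, tolerance = 1e-9)
  expect_equal(j$rank.x, j$rank.y)
  expect_setequal(s1$rank, 1:40) # rank is a permutation
})

test_that("raising a positively weighted score never lowers the IW-score", {
  cfg <- sim_config(missing_rates = rep(0, 11))
  sim <- simulate_scores(300, cfg, seed = 54)
  model <- iw_train(sim, workflow = "K11", seed = 1, transformed = TRUE)
  sys <- names(which.max(model$weights))
  q <- sim[1:5, ]
  bumped <- q
  bumped[[sys]] <- bumped[[sys]] + 10
  s_base <- score_variants(q, model)
  expect_warning(s_bump <- score_variants(bumped, model), "extrapolated")
  expect_true(all(s_bump$iw_score >= s_base$iw_score))
})

test_that("functional variants score higher than non-functional ones", {
  sim <- simulate_scores(4000, seed = 55)
  model <- iw_train(sim, workflow = "K11", seed = 3, transformed = TRUE,
                    reference_size = 1000)
  q <- simulate_scores(2000, seed = 56)
  scored <- suppressWarnings(score_variants(q, model)) # extrapolation expected
  wt <- wilcoxon_rank_sum(scored$iw_score[q$label == 1],
                          scored$iw_score[q$label == 0])
  expect_lt(wt$p_value, 1e-6)
  expect_gt(mean(scored$iw_score[q$label == 1]),
            mean(scored$iw_score[q$label == 0]))
})

test_that("imputed cells are reported per variant", {
  cfg <- sim_config(missing_rates = c(0.5, rep(0, 10)))
  sim <- simulate_scores(300, cfg, seed = 57)
  model <- iw_train(sim, workflow = "K11", seed = 1, transformed = TRUE,
                    reference_size = 150)
  q <- sim[1:30, ]
  scored <- score_variants(q, model)
  miss <- is.na(q[[iw_systems()$system[1]]][1:30])
  has_tag <- grepl(iw_systems()$system[1], scored$imputed_systems)
  expect_equal(has_tag, miss)
})

test_that("a workflow-required system missing from the query is a clear error", {
  sim <- simulate_scores(300, seed = 58)
  model <- iw_train(sim, workflow = "K11", seed = 1, transformed = TRUE,
                    reference_size = 100)
  q <- sim[1:10, ]
  q$gwava_tss <- NULL
  expect_error(score_variants(q, model), "gwava_tss.*N8/N6")
  q2 <- sim[1:10, ]
  q2$gwava_tss <- NA_real_
  expect_error(score_variants(q2, model), "entirely unscored")
})

test_that("local-background significance follows the normal tail", {
  bg <- c(1, 2, 3, 4, 5)
  expect_equal(local_significance(mean(bg), bg)$p_value, 0.5)
  res <- local_significance(mean(bg) + 1.645 * sd(bg), bg)
  expect_equal(res$p_value, 0.05, tolerance = 0.001)
  expect_equal(res$z, 1.645)
  expect_error(local_significance(1, c(1, 2)), "at least 3")
  expect_error(local_significance(1, c(2, 2, 2)), "zero variance")
})
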