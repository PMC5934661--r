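test_that("p-value systems are -log2 transformed with a floor", {
  specs <- tibble::tibble(system = "deepsea", transform = "neg_log2_p",
                          known_only = FALSE)
  d <- tibble::tibble(deepsea = c(0.25, 1.0, 1e-300, NA))
  out <- apply_transforms(d, specs, p_floor = 1e-16)
  expect_equal(out$deepsea[1], 2.0)
  expect_equal(out$deepsea[2], 0.0)
  expect_equal(out$deepsea[3], -log2(1e-16)) # 53.1508...
  expect_true(is.na(out$deepsea[4]))
  expect_error(apply_transforms(tibble::tibble(deepsea = c(0.5, 1.5)), specs),
               "outside \\(0, 1\\]")
  expect_error(apply_transforms(tibble::tibble(deepsea = c(0.5, 0)), specs),
               "outside \\(0, 1\\]")
  # identity systems untouched
  id <- tibble::tibble(cadd = c(-3, 12))
  expect_identical(apply_transforms(id, iw_systems()), id)
})

test_that("standardization uses the sample sd and records extremes", {
  d <- tibble::tibble(a = c(1, 2, 3))
  res <- standardize_training(d)
  expect_equal(res$scores$a, c(-1, 0, 1))
  expect_equal(res$rescale$min_a, 1)
  expect_equal(res$rescale$max_a, 3)
  expect_equal(res$rescale$min_r, -1)
  expect_equal(res$rescale$max_r, 1)

  d2 <- tibble::tibble(b = c(0, 0, 1, 1))
  res2 <- standardize_training(d2)
  expect_equal(res2$rescale$mean, 0.5)
  expect_equal(res2$rescale$sd, 0.5773503, tolerance = 1e-6)
  expect_equal(res2$scores$b, c(-0.8660254, -0.8660254, 0.8660254, 0.8660254),
               tolerance = 1e-6)

  expect_error(standardize_training(tibble::tibble(s = c(5, 5, 5))),
               "zero variance: s")
  expect_error(standardize_training(tibble::tibble(s = c(5, NA, NA))),
               "fewer than 2")
  # training column standardizes to mean 0, var 1; missing untouched
  d3 <- tibble::tibble(c = c(rnorm(50), NA))
  z <- standardize_training(d3)$scores$c
  expect_lt(abs(mean(z, na.rm = TRUE)), 1e-10)
  expect_lt(abs(var(z, na.rm = TRUE) - 1), 1e-10)
  expect_true(is.na(z[51]))
})

test_that("pairwise correlation works over jointly observed rows only", {
  d <- tibble::tibble(a = rnorm(40), b = rnorm(40))
  d$b[1:30] <- d$a[1:30] # identical where joint
  d$a[31:40] <- NA
  cc <- pairwise_correlation(d)
  expect_equal(cc["a", "b"], 1.0)

  withr::with_seed(11, {
    e <- tibble::tibble(x = rnorm(200), y = rnorm(200), z = rnorm(200))
    e$x[sample(200, 60)] <- NA
    e$y[sample(200, 60)] <- NA
    cc <- pairwise_correlation(e)
    joint <- !is.na(e$x) & !is.na(e$y)
    expect_equal(cc["x", "y"], cor(e$x[joint], e$y[joint])) # brute-force filter
    expect_identical(cc, t(cc))
    expect_equal(unname(diag(cc)), rep(1, 3))
  })

  withr::with_seed(12, {
    big <- tibble::tibble(u = rnorm(10000), v = rnorm(10000))
    expect_lt(abs(pairwise_correlation(big)["u", "v"]), 0.05)
  })

  sparse <- tibble::tibble(a = c(1, 2, NA, NA), b = c(NA, NA, 1, 2))
  expect_error(pairwise_correlation(sparse), "jointly observed")
})

test_that("lead-eigenvector weights match hand calculations", {
  m2 <- matrix(c(1, 0.8, 0.8, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  w <- estimate_weights(m2)
  expect_equal(unname(as.numeric(w)), c(1, 1) / sqrt(2), tolerance = 1e-10)
  expect_equal(attr(w, "lead_eigenvalue"), 1.8, tolerance = 1e-12)

  m3 <- diag(3)
  m3[1, 2] <- m3[2, 1] <- 0.9
  w3 <- estimate_weights(m3)
  expect_equal(unname(as.numeric(w3)), c(1 / sqrt(2), 1 / sqrt(2), 0),
               tolerance = 1e-10)
  expect_equal(attr(w3, "lead_eigenvalue"), 1.9, tolerance = 1e-12)
})

test_that("weights agree with the power-iteration oracle on random PSD matrices", {
  withr::with_seed(99, {
    for (i in 1:50) {
      a <- random_psd(11)
      w <- as.numeric(estimate_weights(a))
      o <- power_iteration(a)
      expect_lt(max(abs(w - o$vector)), 1e-8)
      expect_equal(attr(estimate_weights(a), "lead_eigenvalue"), o$value,
                   tolerance = 1e-8)
    }
  })
})

test_that("exchangeable correlation gives exactly equal weights", {
  for (k in c(2, 5, 11)) {
    for (r in c(0.2, 0.7)) {
      m <- matrix(r, k, k)
      diag(m) <- 1
      expect_lt(max(abs(as.numeric(estimate_weights(m)) - 1 / sqrt(k))), 1e-12)
    }
  }
})

test_that("weights are equivariant under system permutation", {
  withr::with_seed(4, {
    a <- random_psd(6)
    dimnames(a) <- list(letters[1:6], letters[1:6])
    perm <- sample(6)
    w <- as.numeric(estimate_weights(a))
    wp <- as.numeric(estimate_weights(a[perm, perm]))
    expect_equal(wp, w[perm], tolerance = 1e-10)
  })
})

test_that("degenerate weight inputs are rejected", {
  asym <- matrix(c(1, 0.5, 0.1, 1), 2, 2)
  expect_error(estimate_weights(asym), "not symmetric")
  expect_error(estimate_weights(diag(2)), "tied")
  expect_error(estimate_weights(matrix(c(1, NA, NA, 1), 2, 2)), "finite")
})

test_that("shifted-lognormal null recovers known parameters and calibrates", {
  withr::with_seed(21, {
    scores <- exp(rnorm(100000)) - 1
    null <- fit_null(scores)
    # the estimated shift is -min(scores)+eps = 1 - min(exp(Z)), which at
    # n = 1e5 undershoots the true shift of 1 by ~0.014 and biases both
    # parameters by ~0.02-0.03; that bias, not sampling noise, sets the bound
    expect_lt(abs(null$meanlog - 0), 0.04)
    expect_lt(abs(null$sdlog - 1), 0.04)
    p_med <- null_pvalue(null, median(scores))
    expect_gt(p_med, 0.45)
    expect_lt(p_med, 0.55)
  })
  expect_error(fit_null(rep(1, 200)), "constant")
  expect_error(fit_null(rnorm(50)), "at least 100")
})

test_that("empirical null follows the rank convention", {
  null <- fit_null(as.numeric(1:200), family = "empirical")
  n <- 200
  expect_equal(null_pvalue(null, 1000), 1 / (n + 1)) # above all scores
  expect_equal(null_pvalue(null, -5), 1)             # below all scores
  expect_equal(null_pvalue(null, 100), (101 + 1) / (n + 1)) # 101 scores >= 100
  s <- sort(rnorm(20))
  p <- null_pvalue(null, s)
  expect_true(all(diff(p) <= 0))
})

test_that("p-values never increase with the score", {
  withr::with_seed(8, {
    null <- fit_null(exp(rnorm(5000)) - 1)
    s <- sort(rnorm(100, sd = 5))
    expect_true(all(diff(null_pvalue(null, s)) <= 0))
    expect_equal(null_pvalue(null, -1e6), 1) # below the fitted support
  })
})

test_that("training is deterministic and workflows subset systems", {
  sim <- simulate_scores(400, seed = 13)
  m1 <- iw_train(sim, workflow = "N6", seed = 5, transformed = TRUE,
                 reference_size = 80)
  m2 <- iw_train(sim, workflow = "N6", seed = 5, transformed = TRUE,
                 reference_size = 80)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$null$sorted_scores, m2$null$sorted_scores)
  expect_identical(m1$reference_pool, m2$reference_pool)

  cfg <- sim_config(missing_rates = rep(0, 11))
  sim_c <- simulate_scores(300, cfg, seed = 13)
  k10 <- iw_train(sim_c, workflow = "K10", seed = 1, transformed = TRUE)
  expect_equal(sort(names(k10$weights)), sort(workflow_systems("K10")))
  expect_false("fitcons" %in% names(k10$weights))
  n8 <- iw_train(sim_c, workflow = "N8", seed = 1, transformed = TRUE)
  expect_false(any(grepl("gwava", names(n8$weights))))
})

test_that("rescale round trip reproduces the training endpoints exactly", {
  withr::with_seed(31, {
    d <- tibble::tibble(s = rnorm(100, 5, 2))
    res <- standardize_training(d)
    p <- res$rescale[1, ]
    expect_identical(rescale_query(p$min_a, p), p$min_r)
    expect_identical(rescale_query(p$max_a, p), p$max_r)
  })
})

test_that("subsampled weights stay close to full-data weights", {
  sim <- simulate_scores(4000, seed = 17)
  rep <- weight_stability(sim, fractions = c(0.5, 1.0), n_repeats = 3, seed = 2)
  expect_equal(nrow(rep), 6L)
  full_rows <- rep[rep$fraction == 1.0, ]
  expect_true(all(full_rows$max_abs_dev == 0)) # identity case
  expect_true(all(rep$ok))
  expect_true(all(rep$max_abs_dev[rep$fraction == 0.5] < 0.1))
  expect_true(all(paste0("dev_", iw_systems()$system) %in% names(rep)))
  expect_error(weight_stability(sim, fractions = c(0, 0.5)), "\\(0, 1\\]")
})
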