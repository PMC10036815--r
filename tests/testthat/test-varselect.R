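test_that("correlation map is a valid 2-D correlation spectrum", {
  set.seed(1)
  X <- matrix(rnorm(60), 12, 5)
  X[, 2] <- 3 * X[, 1] + 1            # proportional columns
  cm <- correlation_map(X)
  expect_equal(dim(cm), c(5L, 5L))
  expect_equal(diag(cm), rep(1, 5))
  expect_equal(cm, t(cm))
  expect_equal(cm[1, 2], 1)

  Xc <- X
  Xc[, 3] <- 2
  expect_warning(cmc <- correlation_map(Xc), "constant")
  expect_true(all(is.na(cmc[3, -3])))
})

test_that("adjacent wavelengths correlate more than distant ones", {
  d <- generate_dataset(small_config(n_samples = 30L, seed = 1L))
  ab <- to_absorbance(average_replicates(d$dataset))
  cm <- correlation_map(ab)
  p <- ncol(cm)
  adj <- mean(abs(cm[cbind(1:(p - 1), 2:p)]))
  set.seed(1)
  far_i <- sample(p, 400, replace = TRUE)
  far_j <- sample(p, 400, replace = TRUE)
  keep <- abs(far_i - far_j) > 30
  dist <- mean(abs(cm[cbind(far_i[keep], far_j[keep])]))
  expect_gt(adj, dist)
})

test_that("reduction percentages follow the subset arithmetic", {
  expect_equal(reduction_percent(992, 2048), 51.56)
  expect_equal(reduction_percent(20, 2048), 99.02)
  expect_equal(reduction_percent(2048, 2048), 0)
  expect_error(reduction_percent(0, 10))
  expect_error(reduction_percent(11, 10))
})

test_that("UVE keeps informative variables and rejects noise", {
  prob <- make_sparse_problem(n = 40L, p = 10L, informative = 5L, seed = 3L)
  res <- uve(prob$X, prob$y, n_latent = 3, seed = 3L)
  expect_true(5L %in% res$selected)
  expect_lt(length(res$selected), 10L)

  # pure-noise response: few real variables survive the noise cutoff
  set.seed(3)
  Xn <- matrix(rnorm(40 * 50), 40, 50)
  yn <- rnorm(40)
  resn <- uve(Xn, yn, n_latent = 5, seed = 3L)
  expect_lte(length(resn$selected), 5L)   # <= 10 % of p = 50
})

test_that("CARS retention ratios honour the boundary conditions", {
  for (case in list(c(50, 2048), c(50, 256), c(10, 64))) {
    edf <- cars_edf(case[1], case[2])
    expect_equal(edf$ratio[1], 1)
    expect_equal(ceiling(edf$ratio[case[1]] * case[2]), 2)
  }
  expect_equal(cars_edf(50, 2048)$ratio[50], 2 / 2048, tolerance = 1e-12)
})

test_that("CARS recovers planted bands and is deterministic under seed", {
  # scatter and baseline are disabled so that density information lives
  # only inside the planted bands (with them on, off-band wavelengths
  # legitimately help by cancelling the baseline); the PLS weighting
  # uses 3 latent variables, the rank of the three-component signal
  cfg <- small_config(n_samples = 120L, seed = 11L,
                      scatter_slope_range = c(1, 1),
                      scatter_offset_range = c(0, 0),
                      baseline_amplitude = 0, replicates_per_sample = 1L)
  d <- generate_dataset(cfg)
  ab <- to_absorbance(d$dataset)
  r1 <- cars(ab$spectra, ab$meta$density, n_runs = 50, n_latent = 3,
             n_cv = 5, seed = 11L)
  r2 <- cars(ab$spectra, ab$meta$density, n_runs = 50, n_latent = 3,
             n_cv = 5, seed = 11L)
  expect_identical(r1$selected, r2$selected)
  expect_gte(in_band_fraction(r1$selected, d$truth), 0.8)
  expect_true(all(r1$selected >= 1 & r1$selected <= 256))
  expect_equal(nrow(r1$history), 50L)
})

test_that("SPA honours cardinality contracts and avoids collinearity", {
  # orthogonal design: every chain reaches full length
  Q <- qr.Q(qr(matrix(rnorm(15 * 8), 15, 8)))
  y <- rnorm(15)
  res <- spa(Q, y, min_vars = 8, max_vars = 8, seed = 1L)
  expect_length(res$selected, 8L)

  # an exactly duplicated column is never selected twice
  set.seed(2)
  X <- matrix(rnorm(40 * 10), 40, 10)
  X[, 7] <- X[, 3]
  y2 <- X %*% rnorm(10) + rnorm(40, 0, 0.1)
  res2 <- spa(X, y2, min_vars = 6, max_vars = 9, seed = 1L)
  expect_false(all(c(3L, 7L) %in% res2$selected))

  # requesting exactly m variables returns exactly m
  d <- generate_dataset(small_config(n_samples = 100L, seed = 2L,
                                     replicates_per_sample = 1L))
  ab <- to_absorbance(d$dataset)
  res3 <- spa(ab$spectra, ab$meta$density, min_vars = 60, max_vars = 60,
              seed = 2L)
  expect_length(res3$selected, 60L)

  # the selected set is linearly independent
  G <- crossprod(scale(ab$spectra[, res3$selected], scale = FALSE))
  expect_gt(min(abs(eigen(G, only.values = TRUE)$values)) /
              max(abs(eigen(G, only.values = TRUE)$values)), 1e-12)
})

test_that("IRIV classifies a copy of the response as strongly informative", {
  set.seed(5)
  X <- matrix(rnorm(60 * 20), 60, 20)
  y <- rnorm(60)
  X[, 4] <- y                       # noise-free duplicate of the response
  res <- iriv(X, y, n_rows_bms = 60, n_latent = 5, n_cv = 5, seed = 5L,
              max_rounds = 6)
  expect_true(4L %in% res$selected)
  expect_gte(res$history$n_strong[1], 1L)
  expect_lte(nrow(res$history), 6L)
})

test_that("IRIV on pure noise selects around the chance level", {
  set.seed(5)
  X <- matrix(rnorm(50 * 24), 50, 24)
  y <- rnorm(50)
  res <- iriv(X, y, n_rows_bms = 60, n_latent = 5, n_cv = 5, seed = 5L,
              max_rounds = 4)
  # with no signal the survivors are an arbitrary small subset
  expect_lt(length(res$selected), 24L)
})

test_that("IRIV recovers planted bands on synthetic spectra", {
  cfg <- small_config(n_samples = 120L, seed = 11L,
                      scatter_slope_range = c(1, 1),
                      scatter_offset_range = c(0, 0),
                      baseline_amplitude = 0, replicates_per_sample = 1L)
  d <- generate_dataset(cfg)
  ab <- to_absorbance(d$dataset)
  res <- iriv(ab$spectra, ab$meta$density, n_rows_bms = 100, n_latent = 10,
              n_cv = 5, seed = 11L)
  expect_gte(in_band_fraction(res$selected, d$truth), 0.8)
})
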