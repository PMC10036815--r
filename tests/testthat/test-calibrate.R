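test_that("PLS collapses to simple regression and to OLS at full rank", {
  set.seed(2)
  # univariate: one latent variable is the least-squares line
  x <- matrix(rnorm(20), ncol = 1)
  y <- 2 + 3 * x[, 1] + rnorm(20, sd = 0.1)
  f <- pls_fit(x, y, 1)
  ls <- stats::lm.fit(cbind(1, x), y)$coefficients
  expect_lt(max(abs(predict(f, x) - cbind(1, x) %*% ls)), 1e-10)

  # full rank: max latent variables reproduce OLS
  X <- matrix(rnorm(40), 10, 4)
  y2 <- rnorm(10)
  ols <- cbind(1, X) %*% stats::lm.fit(cbind(1, X), y2)$coefficients
  expect_lt(max(abs(predict(pls_fit(X, y2, 4), X) - ols)), 1e-8)
  expect_lt(max(abs(predict(pcr_fit(X, y2, 4), X) - ols)), 1e-8)
})

test_that("PLS training error never exceeds PCR at equal component count", {
  for (s in 1:3) {
    set.seed(s)
    X <- matrix(rnorm(200), 20, 10)
    y <- X %*% rnorm(10) + rnorm(20, sd = 0.2)
    for (a in c(2L, 4L)) {
      rp <- sqrt(mean((y - predict(pls_fit(X, y, a), X))^2))
      rc <- sqrt(mean((y - predict(pcr_fit(X, y, a), X))^2))
      expect_lte(rp, rc + 1e-10)
    }
  }
})

test_that("the first PC of isotropic data explains about 1/p variance", {
  set.seed(2)
  X <- matrix(rnorm(4000 * 10), 4000, 10)
  Xc <- sweep(X, 2, colMeans(X))
  ev <- svd(Xc, nu = 0, nv = 0)$d^2
  expect_lt(abs(ev[1] / sum(ev) - 1 / 10), 0.02)
})

test_that("GRNN behaves like Gaussian kernel regression", {
  tX <- matrix(c(0, 2), 2, 1)
  ty <- c(0, 1)
  # equidistant query: exact average, any spread
  for (s in c(0.1, 1, 10))
    expect_equal(grnn_predict(tX, ty, matrix(1, 1, 1), s), 0.5)
  # vanishing spread at a training point: that point's target
  expect_equal(grnn_predict(tX, ty, matrix(0, 1, 1), 1e-4), 0)
  # huge spread: the mean of the targets
  expect_lt(abs(grnn_predict(tX, ty, matrix(0.3, 1, 1), 1e6) - 0.5), 1e-6)
  # weights sum to one: prediction is within the target range
  set.seed(6)
  tX2 <- matrix(rnorm(30), 10, 3)
  ty2 <- rnorm(10)
  q <- matrix(rnorm(15), 5, 3)
  pr <- grnn_predict(tX2, ty2, q, 0.8)
  expect_true(all(pr >= min(ty2) - 1e-12 & pr <= max(ty2) + 1e-12))
})

test_that("SVR fits colinear data and is invariant to row order", {
  x <- matrix(seq(0, 1, length.out = 5), ncol = 1)
  y <- x[, 1]
  f <- svr_fit(x, y, C = 1000, g = 1, epsilon = 1e-4)
  expect_lt(sqrt(mean((predict(f, x) - y)^2)), 1e-3)

  set.seed(7)
  X <- matrix(rnorm(60), 20, 3)
  y2 <- X %*% c(1, -1, 0.5) + rnorm(20, sd = 0.1)
  ord <- sample(20)
  f1 <- svr_fit(X, y2, C = 10, g = 0.3)
  f2 <- svr_fit(X[ord, ], y2[ord], C = 10, g = 0.3)
  q <- matrix(rnorm(15), 5, 3)
  expect_lt(max(abs(predict(f1, q) - predict(f2, q))), 1e-8)
})

test_that("constant-within-epsilon targets give a flat SVR", {
  x <- matrix(rnorm(10), ncol = 1)
  y <- 0.5 + runif(10, -0.005, 0.005)
  f <- svr_fit(x, y, C = 1, g = 1, epsilon = 0.05)
  expect_lt(max(abs(predict(f, x) - mean(range(y)))), 0.02)
})

test_that("cross-validation is deterministic with seed-fixed folds", {
  set.seed(8)
  X <- matrix(rnorm(100), 20, 5)
  y <- X %*% rnorm(5) + rnorm(20, sd = 0.1)
  fit_fun <- function(Xt, yt) pls_fit(Xt, yt, 3)
  a <- cross_validate(fit_fun, X, y, n_folds = 5, seed = 11)
  b <- cross_validate(fit_fun, X, y, n_folds = 5, seed = 11)
  expect_identical(a$cvmse, b$cvmse)
  expect_equal(a$rmsecv, sqrt(a$cvmse))
  # leave-one-out boundary
  loo <- cross_validate(fit_fun, X, y, n_folds = 20, seed = 1)
  expect_length(loo$fold_mse, 20L)
  # a perfect model has zero CV error
  y_lin <- X[, 1]
  perfect <- cross_validate(function(Xt, yt) pls_fit(Xt, yt, 1),
                            X[, 1, drop = FALSE] , y_lin, n_folds = 4, seed = 1)
  expect_lt(perfect$cvmse, 1e-20)
})

test_that("centering and scaling are learned on the training rows only", {
  set.seed(9)
  X <- matrix(rnorm(60), 20, 3)
  y <- X %*% c(1, 2, -1) + rnorm(20, sd = 0.05)
  f <- pls_fit(X, y, 3)
  expect_equal(f$x_center, colMeans(X))
  g <- grnn_fit(X, y, 1)
  expect_equal(g$x_center, colMeans(X))
  # feeding wildly shifted prediction data does not change the stored
  # centering, so predictions shift accordingly rather than re-center
  shifted <- X + 100
  expect_gt(mean(abs(predict(f, shifted) - predict(f, X))), 1)
})

test_that("on strongly nonlinear density the tuned kernel models beat PLS", {
  # concentrations sit near the vertex of the density parabola, so the
  # spectra-density relation has almost no linear component; models are
  # compared on a CARS-selected wavelength subset as in the pipeline
  wins <- 0L
  for (s in 1:3) {
    cfg <- small_config(n_samples = 120L, nonlinearity_strength = 3,
                        density_slopes = c(-5.7, -5.7, -5.7),
                        density_intercept = 3.6,
                        noise_sd = 0.005, seed = 100 + s,
                        replicates_per_sample = 1L)
    d <- generate_dataset(cfg)
    ab <- suppressWarnings(random_split(to_absorbance(d$dataset), 0.7,
                                        seed = s))
    Xc <- get_set(ab, "calibration")$spectra
    yc <- get_set(ab, "calibration")$meta$density
    Xp <- get_set(ab, "prediction")$spectra
    yp <- get_set(ab, "prediction")$meta$density
    sel <- cars(Xc, yc, n_runs = 40, n_latent = 10, n_cv = 5, seed = s)$selected
    Xcs <- Xc[, sel, drop = FALSE]
    Xps <- Xp[, sel, drop = FALSE]
    nl <- select_n_latent(Xcs, yc, max_latent = 10, n_folds = 5,
                          seed = s)$n_latent
    rmse_pls <- sqrt(mean((yp - predict(pls_fit(Xcs, yc, nl), Xps))^2))
    gr <- foa_grnn_train(Xcs, yc, n_cv = 5, n_flies = 10, n_iterations = 30,
                         seed = s)
    rmse_grnn <- sqrt(mean((yp - predict(gr$model, Xps))^2))
    if (rmse_grnn < rmse_pls) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})
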