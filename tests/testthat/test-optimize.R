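test_that("FOA finds a quadratic minimum with a non-increasing trace", {
  opt <- foa_optimize(function(s) (s - 0.3)^2, n_flies = 20,
                      n_iterations = 100, seed = 9L)
  expect_lt(abs(opt$best_value - 0.3), 0.05)
  expect_true(all(diff(opt$trace) <= 0))
  expect_gt(opt$best_value, 0)        # S = 1/distance is always positive
  # determinism
  opt2 <- foa_optimize(function(s) (s - 0.3)^2, n_flies = 20,
                       n_iterations = 100, seed = 9L)
  expect_identical(opt$best_value, opt2$best_value)
})

test_that("FOA-tuned GRNN spread is near the grid-search optimum", {
  cfg <- small_config(n_samples = 50L, seed = 9L, replicates_per_sample = 1L)
  d <- generate_dataset(cfg)
  ab <- to_absorbance(d$dataset)
  sel <- seq(1, 256, by = 8)          # coarse subset keeps the oracle fast
  X <- ab$spectra[, sel]
  y <- ab$meta$density
  tr <- foa_grnn_train(X, y, n_cv = 5, n_flies = 15, n_iterations = 60,
                       seed = 9L)
  # 200-point grid oracle over the spread
  grid <- exp(seq(log(0.01), log(50), length.out = 200))
  cv <- vapply(grid, function(s)
    cross_validate(function(Xt, yt) grnn_fit(Xt, yt, s), X, y,
                   n_folds = 5, seed = 9L)$cvmse, 0)
  best_grid <- min(cv)
  expect_lte(tr$cvmse, best_grid * 1.2)
  expect_true(all(diff(tr$trace) <= 0))
})

test_that("PSO minimizes the sphere function inside the box", {
  cfg <- pso_config(population = 20, max_generation = 100, seed = 13L)
  opt <- pso_optimize(function(p) sum(p^2), lower = c(-5, -5),
                      upper = c(5, 5), config = cfg)
  expect_lt(sqrt(sum(opt$best_point^2)), 1e-2)
  expect_true(all(diff(opt$trace) <= 0))
  expect_true(all(abs(opt$best_point) <= 5))

  # degenerate box returns the single point
  one <- pso_optimize(function(p) sum(p^2), lower = c(1, 2),
                      upper = c(1, 2), config = cfg)
  expect_equal(one$best_point, c(1, 2))
})

test_that("PSO-tuned SVR is close to a log-grid oracle", {
  cfg <- small_config(n_samples = 50L, seed = 13L, replicates_per_sample = 1L)
  d <- generate_dataset(cfg)
  ab <- to_absorbance(d$dataset)
  sel <- seq(1, 256, by = 8)
  X <- ab$spectra[, sel]
  y <- ab$meta$density
  pc <- pso_config(population = 10, max_generation = 15, n_cv = 5, seed = 13L)
  tr <- pso_svm_train(X, y, pc)
  lc <- log10(pc$C_range)
  lg <- log10(pc$g_range)
  grid_cv <- outer(seq(lc[1], lc[2], length.out = 20),
                   seq(lg[1], lg[2], length.out = 20),
                   Vectorize(function(a, b)
                     cross_validate(function(Xt, yt)
                       svr_fit(Xt, yt, 10^a, 10^b), X, y,
                       n_folds = 5, seed = 13L)$cvmse))
  expect_lte(tr$cvmse, min(grid_cv) * 1.1)
  # the tuned model beats the default (C = 1, g = 1/p)
  base <- cross_validate(function(Xt, yt)
    svr_fit(Xt, yt, 1, 1 / ncol(X)), X, y, n_folds = 5, seed = 13L)$cvmse
  expect_lte(tr$cvmse, base)
})

test_that("the Box-Behnken design has the canonical structure", {
  lv <- list(n_cv = c(5, 10, 15), max_generation = c(50, 75, 100),
             population = c(20, 40, 60))
  d <- box_behnken_design(lv, n_center = 5)
  expect_equal(nrow(d$coded), 17L)
  edge <- d$coded[1:12, ]
  expect_true(all(rowSums(edge != 0) == 2L))
  expect_true(all(as.matrix(abs(edge)) %in% c(0, 1)))
  expect_equal(nrow(unique(edge)), 12L)
  expect_true(all(d$coded[13:17, ] == 0))
  # orthogonal linear columns
  cc <- as.matrix(d$coded)
  expect_equal(crossprod(cc)[lower.tri(crossprod(cc))], rep(0, 3))
  # coded -> actual mapping
  expect_equal(unname(unlist(d$actual[13, ])), c(10, 75, 40))
  full <- rbind(c(-1, -1, -1), c(1, 1, 1))
  acts <- sapply(seq_len(3), function(j)
    lv[[j]][2] + full[, j] * (lv[[j]][3] - lv[[j]][1]) / 2)
  expect_equal(unname(acts[1, ]), c(5, 50, 20))
  expect_equal(unname(acts[2, ]), c(15, 100, 60))
})

test_that("quadratic surfaces are recovered exactly and noise is not", {
  d <- box_behnken_design(list(a = c(5, 10, 15), b = c(50, 75, 100),
                               c = c(20, 40, 60)))
  X <- d$coded
  y <- 1 + 2 * X[, 1] + 3 * X[, 3]^2
  s <- fit_quadratic_surface(X, y)
  co <- s$coefficients
  expect_equal(unname(co["(Intercept)"]), 1, tolerance = 1e-8)
  expect_equal(unname(co["x1"]), 2, tolerance = 1e-8)
  expect_equal(unname(co["I(x3^2)"]), 3, tolerance = 1e-8)
  expect_lt(max(abs(co[c("x2", "x1:x2", "x1:x3", "x2:x3", "I(x1^2)",
                         "I(x2^2)")])), 1e-8)

  # constant responses: every non-intercept coefficient vanishes
  s0 <- fit_quadratic_surface(X, rep(2, nrow(X)))
  expect_lt(max(abs(s0$coefficients[-1]), na.rm = TRUE), 1e-10)

  # pure noise: significant terms at alpha = 0.01 are rare
  flagged <- 0L
  for (s_i in 1:25) {
    set.seed(s_i)
    sn <- fit_quadratic_surface(X, rnorm(nrow(X)))
    if (any(sn$p_values[-1] < 0.01, na.rm = TRUE)) flagged <- flagged + 1L
  }
  expect_lte(flagged, 5L)             # >= 80 % of seeds flag nothing
})

test_that("the RSM optimum maps onto the canonical factor settings", {
  lv <- list(n_cv = c(5, 10, 15), max_generation = c(50, 75, 100),
             population = c(20, 40, 60))
  d <- box_behnken_design(lv)
  X <- d$coded
  # convex bowl centered at the origin
  bowl <- fit_quadratic_surface(X, 0.2 + X[, 1]^2 + X[, 2]^2 + X[, 3]^2)
  ob <- rsm_optimize(bowl, lv)
  expect_equal(ob$coded, c(0, 0, 0))
  expect_equal(unname(ob$actual), c(10, 75, 40))
  # surface increasing in every coordinate
  inc <- fit_quadratic_surface(X, 1 + X[, 1] + 2 * X[, 2] + X[, 3])
  oi <- rsm_optimize(inc, lv)
  expect_equal(unname(oi$actual), c(5, 50, 20))
})

test_that("the composed RSM-PSO-SVR trainer improves on the design runs", {
  cfg <- small_config(n_samples = 40L, seed = 13L, replicates_per_sample = 1L)
  d <- generate_dataset(cfg)
  ab <- to_absorbance(d$dataset)
  sel <- seq(1, 256, by = 16)
  X <- ab$spectra[, sel]
  y <- ab$meta$density
  pc <- pso_config(population = 4, max_generation = 4, n_cv = 3, seed = 13L)
  des <- box_behnken_design(list(n_cv = c(3, 4, 5),
                                 max_generation = c(2, 4, 6),
                                 population = c(3, 4, 5)), n_center = 3)
  tr <- rsm_pso_svm_train(X, y, design = des, pso_base_config = pc)
  expect_equal(nrow(tr$report), 15L)   # 12 edge + 3 center runs
  expect_lte(tr$cvmse, stats::median(tr$report$cvmse))
  tr2 <- rsm_pso_svm_train(X, y, design = des, pso_base_config = pc)
  expect_identical(tr$cvmse, tr2$cvmse)
})
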