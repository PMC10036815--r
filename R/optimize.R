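# Hyperparameter optimizers: fruit-fly optimization for the GRNN spread,
# particle-swarm optimization for the SVR (C, g) pair, and Box-Behnken /
# response-surface optimization of the swarm meta-parameters.

#' Fruit-fly optimization of a positive scalar
#'
#' Canonical two-dimensional FOA: each fly perturbs the swarm axis by a
#' uniform step, its candidate value is the reciprocal of its distance to
#' the origin `S = 1/sqrt(X^2 + Y^2)` (hence always positive), and the
#' swarm axis relocates to the best fly found so far. The trace of the
#' best objective value is non-increasing by construction.
#'
#' @param objective function of a positive scalar returning a finite
#'   score; lower is better.
#' @param n_flies swarm size (>= 2).
#' @param n_iterations iterations (>= 1).
#' @param init_axis_range interval for the uniform initial axis
#'   coordinates.
#' @param step_range interval for the per-fly uniform perturbation.
#' @param seed integer seed.
#' @return List with `best_value` (the argmin candidate), `best_score`
#'   and `trace` (best score per iteration).
#' @export
foa_optimize <- function(objective, n_flies = 20L, n_iterations = 100L,
                         init_axis_range = c(0, 1), step_range = c(-1, 1),
                         seed = 1L) {
  if (n_flies < 2L || n_iterations < 1L) stop("invalid FOA configuration")
  if (any(!is.finite(step_range))) stop("step_range must be finite")
  with_seed(seed, {
    axis <- stats::runif(2L, init_axis_range[1], init_axis_range[2])
    best_score <- Inf
    best_value <- NA_real_
    best_pos <- axis
    trace <- numeric(n_iterations)
    for (it in seq_len(n_iterations)) {
      fx <- axis[1] + stats::runif(n_flies, step_range[1], step_range[2])
      fy <- axis[2] + stats::runif(n_flies, step_range[1], step_range[2])
      d <- sqrt(fx^2 + fy^2)
      d[d < 1e-12] <- 1e-12
      s <- 1 / d
      sc <- vapply(s, function(v) {
        val <- objective(v)
        if (!is.finite(val)) Inf else val
      }, 0)
      i <- which.min(sc)
      if (sc[i] < best_score) {
        best_score <- sc[i]
        best_value <- s[i]
        best_pos <- c(fx[i], fy[i])
      }
      axis <- best_pos
      trace[it] <- best_score
    }
    if (!is.finite(best_score))
      stop("objective returned no finite value at any sampled point")
    list(best_value = best_value, best_score = best_score, trace = trace)
  })
}

#' Tune a GRNN spread by fruit-fly optimization
#'
#' The FOA candidate value is used as the GRNN spread; the objective is
#' the cross-validated mean squared error (CVmse) of the GRNN on the
#' calibration data.
#'
#' @param X calibration predictors.
#' @param y calibration response.
#' @param n_cv cross-validation folds of the fitness.
#' @param n_flies,n_iterations,init_axis_range,step_range,seed passed to
#'   [foa_optimize()].
#' @return List with `model` (the [grnn_fit()] at the optimized spread),
#'   `spread`, `cvmse` and the FOA `trace`.
#' @export
foa_grnn_train <- function(X, y, n_cv = 5L, n_flies = 20L,
                           n_iterations = 100L, init_axis_range = c(0, 1),
                           step_range = c(-1, 1), seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  objective <- function(spread)
    cross_validate(function(Xt, yt) grnn_fit(Xt, yt, spread),
                   X, y, n_folds = n_cv, seed = seed)$cvmse
  opt <- foa_optimize(objective, n_flies = n_flies,
                      n_iterations = n_iterations,
                      init_axis_range = init_axis_range,
                      step_range = step_range, seed = seed)
  list(model = grnn_fit(X, y, opt$best_value), spread = opt$best_value,
       cvmse = opt$best_score, trace = opt$trace)
}

#' Particle-swarm configuration
#'
#' @param population swarm size (>= 2).
#' @param max_generation generations (>= 1).
#' @param n_cv cross-validation folds used by SVR fitness functions.
#' @param inertia,cognitive,social the PSO update coefficients w, c1, c2.
#' @param C_range,g_range search intervals for the SVR penalty and kernel
#'   width; the search runs in log10 coordinates.
#' @param seed integer seed.
#' @return A list of class `pso_config`.
#' @export
pso_config <- function(population = 40L, max_generation = 75L, n_cv = 10L,
                       inertia = 0.8, cognitive = 1.5, social = 1.7,
                       C_range = c(2^-5, 2^10), g_range = c(2^-10, 2^5),
                       seed = 1L) {
  if (population < 2L || max_generation < 1L) stop("invalid PSO configuration")
  if (any(C_range <= 0) || any(g_range <= 0)) stop("ranges must be positive")
  structure(list(population = as.integer(population),
                 max_generation = as.integer(max_generation),
                 n_cv = as.integer(n_cv), inertia = inertia,
                 cognitive = cognitive, social = social,
                 C_range = C_range, g_range = g_range,
                 seed = as.integer(seed)),
            class = "pso_config")
}

#' Particle-swarm optimization over a 2-D box
#'
#' Standard velocity/position updates
#' `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)` with positions
#' clamped to the box. The best-so-far trace is non-increasing.
#'
#' @param objective function of a length-2 numeric vector.
#' @param lower,upper box bounds (length 2).
#' @param config a [pso_config()]; `C_range`/`g_range` are ignored here.
#' @return List with `best_point`, `best_score` and `trace`.
#' @export
pso_optimize <- function(objective, lower, upper, config = pso_config()) {
  stopifnot(inherits(config, "pso_config"))
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (any(upper < lower)) stop("upper must be >= lower")
  if (all(upper == lower)) {
    sc <- objective(lower)
    return(list(best_point = lower, best_score = sc, trace = sc))
  }
  np <- config$population
  with_seed(config$seed, {
    pos <- cbind(stats::runif(np, lower[1], upper[1]),
                 stats::runif(np, lower[2], upper[2]))
    span <- upper - lower
    vel <- cbind(stats::runif(np, -span[1], span[1]),
                 stats::runif(np, -span[2], span[2])) * 0.1
    score <- apply(pos, 1L, objective)
    pbest <- pos
    pbest_score <- score
    g <- which.min(score)
    gbest <- pos[g, ]
    gbest_score <- score[g]
    trace <- numeric(config$max_generation)
    for (gen in seq_len(config$max_generation)) {
      r1 <- matrix(stats::runif(np * 2L), np)
      r2 <- matrix(stats::runif(np * 2L), np)
      vel <- config$inertia * vel +
        config$cognitive * r1 * (pbest - pos) +
        config$social * r2 * sweep(-pos, 2L, gbest, `+`)
      pos <- pos + vel
      pos[, 1] <- pmin(pmax(pos[, 1], lower[1]), upper[1])
      pos[, 2] <- pmin(pmax(pos[, 2], lower[2]), upper[2])
      score <- apply(pos, 1L, objective)
      improved <- score < pbest_score
      pbest[improved, ] <- pos[improved, , drop = FALSE]
      pbest_score[improved] <- score[improved]
      if (min(pbest_score) < gbest_score) {
        g <- which.min(pbest_score)
        gbest <- pbest[g, ]
        gbest_score <- pbest_score[g]
      }
      trace[gen] <- gbest_score
    }
    list(best_point = gbest, best_score = gbest_score, trace = trace)
  })
}

#' Tune an SVR by particle-swarm optimization
#'
#' Searches log10(C), log10(g) over the configured ranges; the fitness is
#' the SVR cross-validated mean squared error (CVmse) on the calibration
#' data. Returns the SVR refitted at the best point.
#'
#' @param X calibration predictors.
#' @param y calibration response.
#' @param config a [pso_config()].
#' @param epsilon SVR tube width.
#' @return List with `model`, `C`, `g`, `cvmse` and the PSO `trace`.
#' @export
pso_svm_train <- function(X, y, config = pso_config(), epsilon = 0.01) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  objective <- function(pt)
    cross_validate(function(Xt, yt)
      svr_fit(Xt, yt, C = 10^pt[1], g = 10^pt[2], epsilon = epsilon),
      X, y, n_folds = config$n_cv, seed = config$seed)$cvmse
  opt <- pso_optimize(objective,
                      lower = log10(c(config$C_range[1], config$g_range[1])),
                      upper = log10(c(config$C_range[2], config$g_range[2])),
                      config = config)
  C <- 10^opt$best_point[1]
  g <- 10^opt$best_point[2]
  list(model = svr_fit(X, y, C = C, g = g, epsilon = epsilon),
       C = C, g = g, cvmse = opt$best_score, trace = opt$trace)
}

#' Box-Behnken design for three 3-level factors
#'
#' The 12 edge midpoints (all coded points with two coordinates at +-1
#' and one at 0) plus `n_center` center replicates. Coded levels map
#' affinely onto the actual factor values.
#'
#' @param factor_levels named list of three numeric vectors, each the
#'   factor's values at coded -1, 0, +1.
#' @param n_center number of center-point replicates.
#' @return A list of class `bb_design` with `coded` and `actual` run
#'   matrices (as data frames) and `factors`.
#' @examples
#' d <- box_behnken_design(list(n_cv = c(5, 10, 15),
#'                              max_generation = c(50, 75, 100),
#'                              population = c(20, 40, 60)))
#' nrow(d$coded) # 17
#' @export
box_behnken_design <- function(factor_levels, n_center = 5L) {
  if (length(factor_levels) != 3L)
    stop("Box-Behnken design here requires exactly 3 factors")
  if (!all(vapply(factor_levels, length, 0L) == 3L))
    stop("each factor needs exactly 3 levels (coded -1, 0, +1)")
  pm <- c(-1, -1, 1, 1)
  qm <- c(-1, 1, -1, 1)
  coded <- rbind(
    cbind(pm, qm, 0),
    cbind(pm, 0, qm),
    cbind(0, pm, qm),
    matrix(0, n_center, 3L)
  )
  colnames(coded) <- names(factor_levels)
  actual <- sapply(seq_len(3L), function(j) {
    lv <- factor_levels[[j]]
    center <- lv[2]
    half <- (lv[3] - lv[1]) / 2
    center + coded[, j] * half
  })
  colnames(actual) <- names(factor_levels)
  structure(list(coded = as.data.frame(coded),
                 actual = as.data.frame(actual),
                 factors = factor_levels, n_center = as.integer(n_center)),
            class = "bb_design")
}

#' Fit a full quadratic response surface
#'
#' Least-squares fit of
#' `y = b0 + sum bi xi + sum bij xi xj + sum bii xi^2` on coded design
#' points, with the usual linear-model t-statistics per term.
#'
#' @param design_points data frame or matrix of coded coordinates (3
#'   columns); at least 10 distinct rows.
#' @param responses numeric response per run.
#' @return A list of class `rsm_surface` with `coefficients`, `r2`,
#'   `p_values` and the underlying `lm` fit.
#' @export
fit_quadratic_surface <- function(design_points, responses) {
  Xd <- as.data.frame(design_points)
  if (ncol(Xd) != 3L) stop("expected 3 coded factors")
  names(Xd) <- c("x1", "x2", "x3")
  if (nrow(unique(Xd)) < 10L)
    stop("need at least 10 distinct design points for a full quadratic")
  Xd$y <- as.numeric(responses)
  fit <- stats::lm(y ~ x1 + x2 + x3 + x1:x2 + x1:x3 + x2:x3 +
                     I(x1^2) + I(x2^2) + I(x3^2), data = Xd)
  # an exactly quadratic response gives a perfect fit; the t statistics
  # are meaningless there but the coefficients are still what we report
  sm <- suppressWarnings(summary(fit))
  structure(list(coefficients = stats::coef(fit),
                 r2 = sm$r.squared,
                 p_values = sm$coefficients[, 4L],
                 fit = fit),
            class = "rsm_surface")
}

#' Locate the response-surface minimum
#'
#' Minimizes the fitted quadratic over the coded cube `[-1, 1]^3` on a
#' `grid_n^3` grid, then snaps each coordinate to the nearest feasible
#' integer actual value (the tuned meta-parameters are integer counts).
#'
#' @param surface an `rsm_surface`.
#' @param factor_levels the factor levels used to build the design (for
#'   the coded-to-actual map).
#' @param grid_n grid resolution per axis.
#' @return List with `coded` and `actual` optima and the predicted
#'   minimum `value`.
#' @export
rsm_optimize <- function(surface, factor_levels, grid_n = 41L) {
  stopifnot(inherits(surface, "rsm_surface"))
  g <- seq(-1, 1, length.out = grid_n)
  grid <- expand.grid(x1 = g, x2 = g, x3 = g)
  pred <- stats::predict(surface$fit, grid)
  i <- which.min(pred)
  coded <- as.numeric(grid[i, ])
  actual <- vapply(seq_len(3L), function(j) {
    lv <- factor_levels[[j]]
    val <- lv[2] + coded[j] * (lv[3] - lv[1]) / 2
    round(val)
  }, 0)
  names(actual) <- names(factor_levels)
  list(coded = coded, actual = actual, value = pred[i])
}

#' Train an SVR with Box-Behnken-optimized swarm meta-parameters
#'
#' Runs [pso_svm_train()] once per design run with the run's actual
#' (n_cv, max_generation, population) values, fits the quadratic surface
#' of CVmse over the coded design, locates its minimum, and retrains the
#' PSO-SVR at the optimal meta-parameters.
#'
#' @param X calibration predictors.
#' @param y calibration response.
#' @param design a [box_behnken_design()]; the factors must be named
#'   `n_cv`, `max_generation`, `population`.
#' @param pso_base_config a [pso_config()] supplying everything except
#'   the three tuned meta-parameters.
#' @param epsilon SVR tube width.
#' @return List with `model`, `C`, `g`, `cvmse`, `meta_parameters`, the
#'   fitted `surface` and the per-run `report`.
#' @export
rsm_pso_svm_train <- function(X, y, design = NULL,
                              pso_base_config = pso_config(),
                              epsilon = 0.01) {
  if (is.null(design))
    design <- box_behnken_design(list(n_cv = c(5, 10, 15),
                                      max_generation = c(50, 75, 100),
                                      population = c(20, 40, 60)))
  stopifnot(inherits(design, "bb_design"))
  need <- c("n_cv", "max_generation", "population")
  if (!all(need %in% names(design$actual)))
    stop("design factors must be named n_cv, max_generation, population")
  runs <- nrow(design$actual)
  cvmse <- numeric(runs)
  for (r in seq_len(runs)) {
    cfg <- pso_base_config
    cfg$n_cv <- as.integer(design$actual$n_cv[r])
    cfg$max_generation <- as.integer(design$actual$max_generation[r])
    cfg$population <- as.integer(design$actual$population[r])
    cvmse[r] <- pso_svm_train(X, y, cfg, epsilon = epsilon)$cvmse
  }
  surface <- fit_quadratic_surface(design$coded, cvmse)
  opt <- rsm_optimize(surface, design$factors)
  cfg <- pso_base_config
  cfg$n_cv <- as.integer(opt$actual["n_cv"])
  cfg$max_generation <- as.integer(opt$actual["max_generation"])
  cfg$population <- as.integer(opt$actual["population"])
  final <- pso_svm_train(X, y, cfg, epsilon = epsilon)
  report <- cbind(run = seq_len(runs), design$coded,
                  stats::setNames(design$actual,
                                  paste0(names(design$actual), "_actual")),
                  cvmse = cvmse)
  list(model = final$model, C = final$C, g = final$g, cvmse = final$cvmse,
       meta_parameters = opt$actual, surface = surface, report = report,
       trace = final$trace)
}
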