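# Wavelength selection: UVE, CARS, SPA and IRIV, plus the 2-D
# wavelength-wavelength correlation map and the dimensionality-reduction
# arithmetic. All methods take a plain predictor matrix and response and
# return a `selection_result`; indices are 1-based column positions.

selection_result <- function(method, selected, history, params, seed) {
  if (!length(selected)) stop(method, " selected no variables")
  structure(
    list(method = method, selected = sort(unique(as.integer(selected))),
         history = history, params = params, seed = seed),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d variables selected\n",
              x$method, length(x$selected)))
  invisible(x)
}

#' Wavelength-wavelength correlation map
#'
#' Pearson correlation between every pair of wavelength columns, the 2-D
#' correlation spectrum used to visualize collinearity between adjacent
#' wavelengths. Constant columns yield NA correlations (with a warning).
#'
#' @param ds a [spectra_dataset()] (absorbance mode) or numeric matrix
#'   with at least 3 rows.
#' @return A symmetric p x p correlation matrix with unit diagonal.
#' @export
correlation_map <- function(ds) {
  X <- if (inherits(ds, "spectra_dataset")) {
    if (ds$mode != "absorbance")
      stop("correlation_map() expects absorbance spectra")
    ds$spectra
  } else as.matrix(ds)
  if (nrow(X) < 3L) stop("need at least 3 spectra")
  sds <- apply(X, 2L, stats::sd)
  cm <- suppressWarnings(stats::cor(X))
  if (any(sds < 1e-14)) {
    warning("constant wavelength column(s): correlations set to NA")
    cm[sds < 1e-14, ] <- NA_real_
    cm[, sds < 1e-14] <- NA_real_
  }
  diag(cm) <- 1
  cm
}

#' Dimensionality reduction achieved by a wavelength subset
#'
#' @param n_selected number of retained wavelengths.
#' @param p total number of wavelengths.
#' @return `100 * (1 - n_selected / p)` rounded to 2 decimals.
#' @examples
#' reduction_percent(20, 2048) # 99.02
#' @export
reduction_percent <- function(n_selected, p) {
  if (any(n_selected <= 0) || any(n_selected > p))
    stop("need 0 < n_selected <= p")
  round(100 * (1 - n_selected / p), 2)
}

# safe latent count for an (n, p) problem
cap_latent <- function(n_latent, n, p) max(1L, min(n_latent, p, n - 1L))

#' Uninformative variable elimination
#'
#' Appends `p` artificial noise variables (uniform draws scaled by
#' `noise_scale`), runs leave-one-out PLS regressions, and computes the
#' reliability `c_j = mean(b_j) / sd(b_j)` of every coefficient across
#' the leave-one-out models. Real variables are kept when `|c_j|` exceeds
#' the `cutoff_quantile` quantile of `|c|` over the noise variables.
#'
#' @param X predictor matrix (n >= 10 rows).
#' @param y response vector.
#' @param n_latent PLS latent variables used for the coefficient models.
#' @param noise_scale amplitude of the artificial noise block.
#' @param cutoff_quantile quantile of the noise reliabilities used as
#'   cutoff.
#' @param seed integer seed.
#' @return A `selection_result` with method `"uve"`.
#' @export
uve <- function(X, y, n_latent = 10L, noise_scale = 1e-10,
                cutoff_quantile = 0.99, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 10L) stop("UVE needs at least 10 samples")
  noise <- with_seed(seed, matrix(stats::runif(n * p), n, p) * noise_scale)
  Z <- cbind(X, noise)
  a <- cap_latent(n_latent, n - 1L, ncol(Z))
  B <- matrix(0, n, 2L * p)
  for (i in seq_len(n)) {
    fit <- pls_fit(Z[-i, , drop = FALSE], y[-i], a)
    B[i, ] <- fit$coefficients
  }
  mb <- colMeans(B)
  sb <- apply(B, 2L, stats::sd)
  cj <- mb / sb
  if (any(sb == 0)) {
    warning("zero coefficient spread for some variables; reliability set to Inf")
    cj[sb == 0] <- Inf * sign(mb[sb == 0])
  }
  cutoff <- stats::quantile(abs(cj[(p + 1L):(2L * p)]), cutoff_quantile,
                            names = FALSE)
  keep <- which(abs(cj[seq_len(p)]) > cutoff)
  if (!length(keep)) keep <- which.max(abs(cj[seq_len(p)]))
  history <- data.frame(iteration = 1L, subset_size = length(keep),
                        cutoff = cutoff)
  selection_result("uve", keep, history,
                   list(n_latent = a, noise_scale = noise_scale,
                        cutoff_quantile = cutoff_quantile,
                        reliability = cj[seq_len(p)]),
                   seed)
}

#' Competitive adaptive reweighted sampling
#'
#' `n_runs` Monte-Carlo iterations: each draws `ceil(sample_ratio * n)`
#' samples, fits PLS on the surviving variables, and weights variables by
#' their absolute regression coefficients. An exponentially decreasing
#' forced-retention ratio `r_i = a exp(-k i)` (calibrated so `r_1 = 1`
#' and the final subset has 2 variables) keeps the top-weighted
#' variables, followed by adaptive reweighted sampling (a weighted draw
#' with replacement whose support is kept). The subset with the lowest
#' cross-validated RMSECV over all iterations is returned.
#'
#' @param X predictor matrix.
#' @param y response vector.
#' @param n_runs number of Monte-Carlo iterations N (>= 2).
#' @param n_latent PLS latent variables.
#' @param sample_ratio fraction of samples drawn per iteration.
#' @param n_cv cross-validation folds for the RMSECV scoring.
#' @param seed integer seed.
#' @return A `selection_result` with method `"cars"`; `history` records
#'   subset size and RMSECV per iteration.
#' @export
cars <- function(X, y, n_runs = 50L, n_latent = 10L, sample_ratio = 0.8,
                 n_cv = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (n_runs < 2L) stop("n_runs must be >= 2")
  if (p < 3L) stop("CARS needs at least 3 variables")
  edf <- cars_edf(n_runs, p)
  subsets <- vector("list", n_runs)
  rmsecv <- numeric(n_runs)
  sizes <- integer(n_runs)
  current <- seq_len(p)
  with_seed(seed, {
    for (i in seq_len(n_runs)) {
      rows <- sample.int(n, ceiling(sample_ratio * n))
      a <- cap_latent(n_latent, length(rows), length(current))
      fit <- pls_fit(X[rows, current, drop = FALSE], y[rows], a)
      w <- abs(fit$coefficients)
      # enforced retention by exponentially decreasing ratio
      keep_n <- max(2L, min(length(current), edf$sizes[i]))
      ord <- order(w, decreasing = TRUE)
      top <- current[ord[seq_len(keep_n)]]
      w_top <- w[ord[seq_len(keep_n)]]
      # adaptive reweighted sampling: weighted draw with replacement,
      # the drawn support becomes the subset
      if (sum(w_top) > 0) {
        drawn <- sample(top, size = keep_n, replace = TRUE,
                        prob = w_top / sum(w_top))
        subset <- sort(unique(drawn))
      } else subset <- sort(top)
      if (length(subset) < 2L) subset <- sort(top)[seq_len(2L)]
      a2 <- cap_latent(n_latent, n - ceiling(n / n_cv), length(subset))
      # common folds across iterations so subsets are compared on the
      # same partition rather than on fold-assignment noise
      rmsecv[i] <- cross_validate(function(Xt, yt)
        pls_fit(Xt, yt, cap_latent(a2, nrow(Xt), ncol(Xt))),
        X[, subset, drop = FALSE], y, n_folds = n_cv, seed = seed)$rmsecv
      subsets[[i]] <- subset
      sizes[i] <- length(subset)
      current <- subset
    }
  })
  best <- which.min(rmsecv)
  history <- data.frame(iteration = seq_len(n_runs), subset_size = sizes,
                        retention_ratio = edf$ratio, rmsecv = rmsecv)
  selection_result("cars", subsets[[best]], history,
                   list(n_runs = n_runs, n_latent = n_latent,
                        sample_ratio = sample_ratio, n_cv = n_cv,
                        best_iteration = best),
                   seed)
}

#' Exponentially decreasing retention ratios for CARS
#'
#' Solves `a exp(-k)` through `a exp(-k N)` with boundary conditions
#' `r_1 = 1` and `r_N = 2/p`, so iteration 1 keeps every variable and the
#' final forced subset has 2 variables.
#'
#' @param n_runs number of iterations N.
#' @param p number of variables.
#' @return List with `a`, `k` and the ratio vector (`ratio[i]` for
#'   iteration i).
#' @export
cars_edf <- function(n_runs, p) {
  if (p < 3L) stop("p must be >= 3")
  k <- log(p / 2) / (n_runs - 1L)
  a <- exp(k)                 # so a * exp(-k * 1) = 1
  i <- seq_len(n_runs)
  ratio <- a * exp(-k * i)
  ratio[1] <- 1
  ratio[n_runs] <- 2 / p
  # forced subset sizes; the tolerant ceiling keeps the algebraic
  # endpoints (p at iteration 1, 2 at iteration N) despite roundoff
  list(a = a, k = k, ratio = ratio,
       sizes = pmax(2, ceiling(ratio * p - 1e-9)))
}

#' Successive projections algorithm
#'
#' Forward selection minimizing collinearity: starting from each
#' candidate column, the chain repeatedly appends the column with the
#' largest norm of its projection onto the orthogonal complement of the
#' chosen set. Chains of every length in `min_vars..max_vars` from every
#' start are scored by validation-set RMSE of a multiple linear
#' regression; the best-scoring chain is returned.
#'
#' @param X predictor matrix.
#' @param y response vector.
#' @param min_vars,max_vars chain lengths scanned
#'   (`max_vars <= min(n - 1, p)`).
#' @param validation_fraction fraction of samples held out to score
#'   chains.
#' @param seed integer seed (validation split).
#' @return A `selection_result` with method `"spa"`.
#' @export
spa <- function(X, y, min_vars = 5L, max_vars = 30L,
                validation_fraction = 0.25, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (max_vars > min(n - 1L, p)) stop("max_vars must be <= min(n-1, p)")
  if (min_vars > max_vars) stop("min_vars must be <= max_vars")
  n_val <- max(2L, round(validation_fraction * n))
  if (max_vars > n - n_val - 1L)
    stop("max_vars exceeds the rank of the training partition (",
         n - n_val - 1L, " after holding out ", n_val, " validation rows)")
  val <- with_seed(seed, sample.int(n, n_val))
  Xt <- X[-val, , drop = FALSE]
  yt <- y[-val]
  Xv <- X[val, , drop = FALSE]
  yv <- y[val]
  Xc <- sweep(Xt, 2L, colMeans(Xt))      # projections on centered columns
  chains <- vector("list", p)
  for (start in seq_len(p)) {
    proj <- Xc
    chain <- integer(max_vars)
    chain[1L] <- start
    for (m in 2L:max_vars) {
      v <- proj[, chain[m - 1L]]
      nv <- sum(v^2)
      if (nv < 1e-20) { chain <- chain[seq_len(m - 1L)]; break }
      proj <- proj - (v %*% crossprod(v, proj)) / nv
      norms <- colSums(proj^2)
      norms[chain[seq_len(m - 1L)]] <- -1
      cand <- which.max(norms)
      if (norms[cand] < 1e-20) { chain <- chain[seq_len(m - 1L)]; break }
      chain[m] <- cand
    }
    chains[[start]] <- chain[chain > 0L]
  }
  best <- NULL
  best_rmse <- Inf
  history <- list()
  for (start in seq_len(p)) {
    chain <- chains[[start]]
    if (length(chain) < min_vars) next   # rank-deficient start
    for (m in min_vars:min(max_vars, length(chain))) {
      sel <- chain[seq_len(m)]
      fit <- stats::lm.fit(cbind(1, Xt[, sel, drop = FALSE]), yt)
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0           # aliased columns contribute nothing
      pred <- cbind(1, Xv[, sel, drop = FALSE]) %*% beta
      rmse <- sqrt(mean((yv - pred)^2))
      history[[length(history) + 1L]] <-
        data.frame(start = start, subset_size = m, rmse = rmse)
      if (rmse < best_rmse) { best_rmse <- rmse; best <- sel }
    }
  }
  selection_result("spa", best, do.call(rbind, history),
                   list(min_vars = min_vars, max_vars = max_vars,
                        validation_fraction = validation_fraction,
                        best_rmse = best_rmse),
                   seed)
}

#' Iteratively retains informative variables
#'
#' Each round draws a binary sampling matrix (inclusion probability 0.5)
#' over the surviving variables and computes a PLS RMSECV per row. For
#' every variable the difference
#' `DMEAN = mean(RMSECV | excluded) - mean(RMSECV | included)` and a
#' two-sample t-test p-value classify it as strongly informative
#' (`DMEAN > 0`, p < alpha), weakly informative (`DMEAN > 0`,
#' p >= alpha), uninformative or interfering; only informative variables
#' survive to the next round. Rounds stop when nothing is dropped or
#' `max_rounds` is reached, then a greedy backward elimination removes
#' survivors whose removal lowers the RMSECV.
#'
#' @param X predictor matrix (p >= 4).
#' @param y response vector.
#' @param n_rows_bms rows of the binary sampling matrix per round
#'   (>= 50).
#' @param n_latent PLS latent variables.
#' @param n_cv cross-validation folds.
#' @param alpha significance level of the t-test.
#' @param max_rounds cap on the number of rounds.
#' @param seed integer seed.
#' @return A `selection_result` with method `"iriv"`; `history` records
#'   per-round subset sizes and mean RMSECV.
#' @export
iriv <- function(X, y, n_rows_bms = 500L, n_latent = 10L, n_cv = 5L,
                 alpha = 0.05, max_rounds = 10L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (p < 4L) stop("IRIV needs at least 4 variables")
  if (n_rows_bms < 50L) stop("n_rows_bms must be >= 50")
  current <- seq_len(p)
  history <- list()
  round_i <- 0L
  with_seed(seed, {
    repeat {
      round_i <- round_i + 1L
      pc <- length(current)
      Bm <- matrix(stats::runif(n_rows_bms * pc) < 0.5, n_rows_bms, pc)
      # guarantee usable rows
      empty <- rowSums(Bm) < 2L
      Bm[empty, ] <- TRUE
      rm_cv <- numeric(n_rows_bms)
      for (r in seq_len(n_rows_bms)) {
        cols <- current[Bm[r, ]]
        a <- cap_latent(n_latent, n - ceiling(n / n_cv), length(cols))
        rm_cv[r] <- cross_validate(function(Xt, yt)
          pls_fit(Xt, yt, cap_latent(a, nrow(Xt), ncol(Xt))),
          X[, cols, drop = FALSE], y, n_folds = n_cv, seed = seed + r)$rmsecv
      }
      dmean <- numeric(pc)
      pval <- numeric(pc)
      for (j in seq_len(pc)) {
        inc <- rm_cv[Bm[, j]]
        exc <- rm_cv[!Bm[, j]]
        if (length(inc) < 2L || length(exc) < 2L) {
          dmean[j] <- 0; pval[j] <- 1
        } else {
          dmean[j] <- mean(exc) - mean(inc)
          pval[j] <- stats::t.test(exc, inc)$p.value
        }
      }
      keep <- dmean > 0
      history[[round_i]] <- data.frame(
        round = round_i, subset_size = pc, mean_rmsecv = mean(rm_cv),
        n_strong = sum(keep & pval < alpha),
        n_weak = sum(keep & pval >= alpha))
      if (!any(keep))
        stop("IRIV dropped all variables; consider a smaller alpha")
      new_current <- current[keep]
      if (length(new_current) == length(current) || round_i >= max_rounds ||
          length(new_current) <= 2L) {
        current <- new_current
        break
      }
      current <- new_current
    }
    # backward elimination: greedily drop variables that reduce RMSECV
    score <- function(cols) {
      a <- cap_latent(n_latent, n - ceiling(n / n_cv), length(cols))
      cross_validate(function(Xt, yt)
        pls_fit(Xt, yt, cap_latent(a, nrow(Xt), ncol(Xt))),
        X[, cols, drop = FALSE], y, n_folds = n_cv, seed = seed)$rmsecv
    }
    base <- score(current)
    while (length(current) > 2L) {
      trial <- vapply(seq_along(current),
                      function(j) score(current[-j]), 0)
      if (min(trial) < base) {
        base <- min(trial)
        current <- current[-which.min(trial)]
      } else break
    }
  })
  selection_result("iriv", current, do.call(rbind, history),
                   list(n_rows_bms = n_rows_bms, n_latent = n_latent,
                        n_cv = n_cv, alpha = alpha, max_rounds = max_rounds),
                   seed)
}
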