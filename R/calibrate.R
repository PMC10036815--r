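# Calibration models: PLS (NIPALS), PCR, GRNN and epsilon-SVR, plus the
# cross-validation utilities used by the selection and tuning code.
#
# PLS and PCR work on column-centered predictors; the distance-based
# models (GRNN, SVR) standardize predictors to unit variance. Centering
# and scaling parameters are always learned on the calibration rows and
# reapplied, never recomputed, at prediction time.

#' Fit a PLS1 regression by NIPALS
#'
#' Column-centers `X` and `y`, then extracts `n_latent` latent variables:
#' per component the weight vector `w = X'y / |X'y|`, scores `t = Xw`,
#' loadings `p = X't / t't`, regression `q = y't / t't`, with deflation of
#' `X` and `y`. Regression coefficients are `B = W (P'W)^{-1} q`.
#'
#' @param X predictor matrix (samples x variables).
#' @param y response vector.
#' @param n_latent number of latent variables, `1 <= n_latent <= min(n-1, p)`.
#' @return A `calibration_model` of kind `"pls"`.
#' @export
pls_fit <- function(X, y, n_latent) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("X and y sizes disagree")
  if (stats::var(y) == 0) stop("response has zero variance")
  n_latent <- as.integer(n_latent)
  if (n_latent < 1L || n_latent > min(n - 1L, p))
    stop("n_latent must be in 1..min(n-1, p)")
  x_center <- colMeans(X)
  y_center <- mean(y)
  Xc <- sweep(X, 2L, x_center)
  yc <- y - y_center
  W <- matrix(0, p, n_latent)
  P <- matrix(0, p, n_latent)
  q <- numeric(n_latent)
  for (a in seq_len(n_latent)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) {            # response fully deflated; stop early
      W <- W[, seq_len(a - 1L), drop = FALSE]
      P <- P[, seq_len(a - 1L), drop = FALSE]
      q <- q[seq_len(a - 1L)]
      n_latent <- a - 1L
      break
    }
    w <- w / nw
    t <- as.vector(Xc %*% w)
    tt <- sum(t^2)
    pp <- crossprod(Xc, t) / tt
    qq <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, pp)
    yc <- yc - qq * t
    W[, a] <- w
    P[, a] <- pp
    q[a] <- qq
  }
  if (n_latent == 0L) stop("no usable latent variable (X'y is zero)")
  B <- W %*% solve(crossprod(P, W), q)
  structure(
    list(kind = "pls", n_latent = n_latent, coefficients = as.vector(B),
         x_center = x_center, y_center = y_center),
    class = c("pls_model", "calibration_model")
  )
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  object$y_center + as.vector(sweep(X, 2L, object$x_center) %*% object$coefficients)
}

#' Fit a principal component regression
#'
#' Principal components of column-centered `X` (via SVD), then ordinary
#' least squares of `y` on the first `n_components` scores.
#'
#' @param X predictor matrix.
#' @param y response vector.
#' @param n_components number of principal components.
#' @return A `calibration_model` of kind `"pcr"`.
#' @export
pcr_fit <- function(X, y, n_components) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop("X and y sizes disagree")
  if (stats::var(y) == 0) stop("response has zero variance")
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > min(n - 1L, ncol(X)))
    stop("n_components must be in 1..min(n-1, p)")
  x_center <- colMeans(X)
  y_center <- mean(y)
  Xc <- sweep(X, 2L, x_center)
  sv <- svd(Xc, nu = 0, nv = n_components)
  keep <- sv$d[seq_len(n_components)] > 1e-10 * sv$d[1]
  V <- sv$v[, keep, drop = FALSE]
  scores <- Xc %*% V
  gamma <- solve(crossprod(scores), crossprod(scores, y - y_center))
  structure(
    list(kind = "pcr", n_components = sum(keep),
         coefficients = as.vector(V %*% gamma),
         x_center = x_center, y_center = y_center),
    class = c("pcr_model", "calibration_model")
  )
}

#' @export
predict.pcr_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  object$y_center + as.vector(sweep(X, 2L, object$x_center) %*% object$coefficients)
}

#' Generalized regression neural network prediction
#'
#' The GRNN is Nadaraya-Watson kernel regression with a Gaussian kernel:
#' `yhat(x) = sum_i y_i K_i / sum_i K_i` with
#' `K_i = exp(-|x - x_i|^2 / (2 sigma^2))`. Exponents are stabilized by
#' subtracting the per-query maximum; if every kernel weight underflows
#' the nearest training point's target is returned with a warning.
#'
#' @param train_X,train_y training references.
#' @param query_X rows to predict.
#' @param spread the kernel width sigma (> 0).
#' @return Predicted values for the query rows.
#' @export
grnn_predict <- function(train_X, train_y, query_X, spread) {
  if (spread <= 0) stop("spread must be positive")
  train_X <- as.matrix(train_X)
  query_X <- as.matrix(query_X)
  d2 <- distance_sq(query_X, train_X)
  expo <- -d2 / (2 * spread^2)
  shift <- apply(expo, 1L, max)
  w <- exp(expo - shift)
  denom <- rowSums(w)
  bad <- !is.finite(denom) | denom == 0
  out <- as.vector(w %*% train_y) / denom
  if (any(bad)) {
    warning("kernel weights underflowed; using nearest neighbour for ",
            sum(bad), " query point(s)")
    nn <- apply(d2[bad, , drop = FALSE], 1L, which.min)
    out[bad] <- train_y[nn]
  }
  out
}

# squared Euclidean distances between row sets
distance_sq <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Fit a GRNN calibration model
#'
#' Stores the (standardized) training references and the spread; all the
#' computation happens at prediction time via [grnn_predict()].
#'
#' @param X training predictors.
#' @param y training response.
#' @param spread Gaussian kernel width on the standardized predictor scale.
#' @return A `calibration_model` of kind `"grnn"`.
#' @export
grnn_fit <- function(X, y, spread) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl < 1e-12] <- 1
  structure(
    list(kind = "grnn", spread = spread,
         train_X = sweep(sweep(X, 2L, ctr), 2L, scl, `/`),
         train_y = as.numeric(y), x_center = ctr, x_scale = scl),
    class = c("grnn_model", "calibration_model")
  )
}

#' @export
predict.grnn_model <- function(object, newdata, ...) {
  Q <- sweep(sweep(as.matrix(newdata), 2L, object$x_center), 2L,
             object$x_scale, `/`)
  grnn_predict(object$train_X, object$train_y, Q, object$spread)
}

#' Fit an epsilon-SVR with RBF kernel
#'
#' Support-vector regression with the epsilon-insensitive loss and kernel
#' `k(u, v) = exp(-g |u - v|^2)`, solved by the e1071/libsvm dual solver.
#' Predictors are standardized with training-set parameters.
#'
#' @param X training predictors.
#' @param y training response.
#' @param C penalty factor (> 0).
#' @param g RBF kernel width parameter (> 0).
#' @param epsilon width of the insensitive tube (>= 0); the default 0.01
#'   is on the scale of the standardized response.
#' @return A `calibration_model` of kind `"svr"`.
#' @export
svr_fit <- function(X, y, C, g, epsilon = 0.01) {
  if (C <= 0 || g <= 0 || epsilon < 0) stop("invalid SVR hyperparameters")
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, `/`)
  y <- as.numeric(y)
  fit <- e1071::svm(x = Xs, y = y, type = "eps-regression",
                    kernel = "radial", cost = C, gamma = g,
                    epsilon = epsilon, scale = FALSE, fitted = FALSE)
  # when every target sits inside the epsilon tube the dual has no
  # support vectors; the minimizer is then any constant in the tube
  # intersection, taken here as the midrange of y
  constant <- if (fit$tot.nSV == 0L) mean(range(y)) else NULL
  structure(
    list(kind = "svr", C = C, g = g, epsilon = epsilon, fit = fit,
         constant = constant, x_center = ctr, x_scale = scl),
    class = c("svr_model", "calibration_model")
  )
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$constant))
    return(rep(object$constant, nrow(newdata)))
  Q <- sweep(sweep(newdata, 2L, object$x_center), 2L,
             object$x_scale, `/`)
  as.vector(stats::predict(object$fit, Q))
}

#' Cross-validate a model-fitting function
#'
#' Deterministic k-fold cross-validation. `fit_fun(X, y)` must return a
#' model with a `predict` method.
#'
#' @param fit_fun function of `(X, y)` returning a fitted model.
#' @param X predictor matrix.
#' @param y response vector.
#' @param n_folds number of folds (2..n).
#' @param seed integer seed fixing the fold assignment.
#' @return List with `cvmse` (mean over folds of the fold mean squared
#'   error), `rmsecv = sqrt(cvmse)`, `predictions` (out-of-fold, in input
#'   order) and `fold_mse`.
#' @export
cross_validate <- function(fit_fun, X, y, n_folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  folds <- make_folds(nrow(X), n_folds, seed)
  preds <- numeric(length(y))
  fold_mse <- numeric(length(folds))
  for (i in seq_along(folds)) {
    hold <- folds[[i]]
    model <- fit_fun(X[-hold, , drop = FALSE], y[-hold])
    preds[hold] <- stats::predict(model, X[hold, , drop = FALSE])
    fold_mse[i] <- mean((y[hold] - preds[hold])^2)
  }
  cvmse <- mean(fold_mse)
  list(cvmse = cvmse, rmsecv = sqrt(cvmse), predictions = preds,
       fold_mse = fold_mse)
}

#' Choose the PLS latent-variable count by cross-validation
#'
#' Scans 1..`max_latent` latent variables and returns the count with the
#' lowest RMSECV (the smallest count within ties).
#'
#' @param X predictor matrix.
#' @param y response vector.
#' @param max_latent upper bound on the scan (default 15, capped by data
#'   size).
#' @param n_folds,seed cross-validation controls.
#' @return List with `n_latent`, `rmsecv` and the full `scan` table.
#' @export
select_n_latent <- function(X, y, max_latent = 15L, n_folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  cap <- min(max_latent, ncol(X), n - ceiling(n / n_folds) - 1L)
  cap <- max(cap, 1L)
  rmsecv <- vapply(seq_len(cap), function(a) {
    cross_validate(function(Xt, yt) pls_fit(Xt, yt, min(a, ncol(Xt), nrow(Xt) - 1L)),
                   X, y, n_folds = n_folds, seed = seed)$rmsecv
  }, 0)
  best <- which.min(rmsecv)
  list(n_latent = best, rmsecv = rmsecv[best],
       scan = data.frame(n_latent = seq_len(cap), rmsecv = rmsecv))
}
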