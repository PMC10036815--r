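#' Calibration and prediction performance metrics
#'
#' Computes the four figures of merit used throughout the package to judge
#' a density model: the coefficient of determination R2, the root mean
#' square error (RMSE, g/cm3), the relative prediction deviation
#' (RPD = SD(y)/RMSE) and the relative standard deviation
#' (RSD = 100 * RMSE / mean(y), in percent). The standard deviation in RPD
#' uses the population convention (denominator n), which makes the identity
#' RPD = (1 - R2)^(-1/2) exact whenever both are computed on the same data.
#'
#' @param reference observed densities (g/cm3).
#' @param predicted model predictions, same length.
#' @return An object of class `model_metrics`: a list with elements `r2`,
#'   `rmse`, `rpd`, `rsd` and `n`. A perfect fit reports `rpd = Inf`.
#' @examples
#' y <- c(0.6, 0.7, 0.8, 0.9)
#' compute_metrics(y, y + 0.01)
#' @export
compute_metrics <- function(reference, predicted) {
  y <- as.numeric(reference)
  yhat <- as.numeric(predicted)
  n <- length(y)
  if (length(yhat) != n) stop("reference and predicted lengths differ")
  if (n < 2L) stop("need at least 2 observations")
  if (any(!is.finite(y)) || any(!is.finite(yhat)))
    stop("non-finite values in reference or predicted")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("reference values are constant")
  ss_res <- sum((y - yhat)^2)
  rmse <- sqrt(ss_res / n)
  sd_pop <- sqrt(ss_tot / n)
  structure(
    list(
      r2 = 1 - ss_res / ss_tot,
      rmse = rmse,
      rpd = if (rmse == 0) Inf else sd_pop / rmse,
      rsd = 100 * rmse / mean(y),
      n = n
    ),
    class = "model_metrics"
  )
}

#' @export
print.model_metrics <- function(x, ...) {
  cat(sprintf("R2 = %.3f  RMSE = %.3f  RPD = %.3f  RSD = %.3f%%  (n = %d)\n",
              x$r2, x$rmse, x$rpd, x$rsd, x$n))
  invisible(x)
}

#' Relative prediction deviation implied by R2
#'
#' With the population-SD convention, RPD and R2 computed on the same data
#' are linked by RPD = (1 - R2)^(-1/2). Useful to cross-check reported
#' metric pairs.
#'
#' @param r2 coefficient of determination, `r2 < 1`.
#' @return The implied RPD.
#' @examples
#' rpd_from_r2(0.812) # 2.306
#' @export
rpd_from_r2 <- function(r2) {
  if (any(r2 >= 1)) stop("r2 must be < 1")
  1 / sqrt(1 - r2)
}

#' Convert metrics to a one-row data frame
#'
#' @param x a `model_metrics` object.
#' @param row.names,optional,... passed through for the generic signature.
#' @return A one-row data frame with columns `r2`, `rmse`, `rpd`, `rsd`, `n`.
#' @export
as.data.frame.model_metrics <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(r2 = x$r2, rmse = x$rmse, rpd = x$rpd, rsd = x$rsd, n = x$n)
}
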