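# Scatter-correction preprocessing: MSC and SNV.

#' Multiplicative scatter correction
#'
#' Each spectrum `x` is regressed on a reference spectrum,
#' `x ~ a + b * reference`, and corrected to `(x - a) / b`. The reference
#' defaults to the mean spectrum of the calibration rows (all rows if no
#' split is assigned) and is stored in the result so prediction-set
#' spectra are corrected against the same reference.
#'
#' @param ds a [spectra_dataset()].
#' @param reference reference spectrum (numeric vector) or `NULL` for the
#'   calibration-set mean.
#' @return The corrected dataset, with the reference stored in
#'   `attr(, "msc_reference")`.
#' @export
msc <- function(ds, reference = NULL) {
  stopifnot(inherits(ds, "spectra_dataset"))
  X <- ds$spectra
  if (is.null(reference)) {
    cal <- ds$meta$set == "calibration"
    rows <- if (any(cal)) X[cal, , drop = FALSE] else X
    if (nrow(rows) < 2L)
      stop("need at least 2 spectra to form a mean reference")
    reference <- colMeans(rows)
  }
  if (length(reference) != ncol(X))
    stop("reference length must match the wavelength grid")
  ref_c <- reference - mean(reference)
  denom <- sum(ref_c^2)
  if (denom < 1e-24) stop("reference spectrum is constant")
  out <- ds
  for (i in seq_len(nrow(X))) {
    b <- sum((X[i, ] - mean(X[i, ])) * ref_c) / denom
    if (abs(b) < 1e-12)
      stop("spectrum ", i, " has no multiplicative relation to the reference")
    a <- mean(X[i, ]) - b * mean(reference)
    out$spectra[i, ] <- (X[i, ] - a) / b
  }
  attr(out, "msc_reference") <- reference
  out
}

#' Standard normal variate transform
#'
#' Each spectrum is standardized to mean 0 and standard deviation 1
#' (denominator n - 1), removing additive offsets and multiplicative
#' scaling per spectrum.
#'
#' @param ds a [spectra_dataset()].
#' @return The transformed dataset.
#' @export
snv <- function(ds) {
  stopifnot(inherits(ds, "spectra_dataset"))
  s <- apply(ds$spectra, 1L, stats::sd)
  if (any(s < 1e-14)) stop("constant spectrum cannot be SNV-transformed")
  ds$spectra <- (ds$spectra - rowMeans(ds$spectra)) / s
  ds
}
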