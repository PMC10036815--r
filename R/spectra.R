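#' Construct a spectra dataset
#'
#' The central container of the package: a matrix of Vis-NIR spectra on a
#' common wavelength grid together with per-row metadata (sample id, species,
#' location, replicate number, wood density in g/cm3) and a mode flag saying
#' whether values are reflectance (in (0, 1]) or absorbance (log10(1/R)).
#'
#' @param wavelengths strictly increasing numeric grid in nm.
#' @param spectra numeric matrix, one row per measured spectrum, one column
#'   per wavelength.
#' @param density numeric vector of wood densities in g/cm3, one per row.
#' @param sample_id character or integer ids; rows sharing an id are
#'   replicate scans of the same physical sample.
#' @param species,location character labels, recycled to the row count.
#' @param replicate integer replicate number within a sample.
#' @param mode `"reflectance"` or `"absorbance"`.
#' @param set split membership per row: `"calibration"`, `"prediction"` or
#'   `"unassigned"`.
#' @return An object of class `spectra_dataset`.
#' @export
spectra_dataset <- function(wavelengths, spectra, density,
                            sample_id = seq_len(nrow(spectra)),
                            species = "unknown", location = "unknown",
                            replicate = 1L,
                            mode = c("reflectance", "absorbance"),
                            set = "unassigned") {
  mode <- match.arg(mode)
  spectra <- as.matrix(spectra)
  wavelengths <- as.numeric(wavelengths)
  n <- nrow(spectra)
  if (length(wavelengths) != ncol(spectra))
    stop("length(wavelengths) must equal ncol(spectra)")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (length(density) != n)
    stop("density must have one value per spectrum row")
  if (mode == "reflectance") {
    if (any(!is.finite(spectra)) || any(spectra <= 0) || any(spectra > 1))
      stop("reflectance values must lie in (0, 1]")
  }
  meta <- data.frame(
    sample_id = as.character(rep_len(sample_id, n)),
    species = as.character(rep_len(species, n)),
    location = as.character(rep_len(location, n)),
    replicate = as.integer(rep_len(replicate, n)),
    density = as.numeric(density),
    set = as.character(rep_len(set, n)),
    stringsAsFactors = FALSE
  )
  bad_set <- setdiff(unique(meta$set), c("calibration", "prediction", "unassigned"))
  if (length(bad_set))
    stop("unknown set label(s): ", paste(bad_set, collapse = ", "))
  dimnames(spectra) <- NULL
  structure(
    list(wavelengths = wavelengths, spectra = spectra, meta = meta, mode = mode),
    class = "spectra_dataset"
  )
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat(sprintf(
    "<spectra_dataset> %d spectra x %d wavelengths (%.0f-%.0f nm), mode=%s\n",
    nrow(x$spectra), length(x$wavelengths),
    min(x$wavelengths), max(x$wavelengths), x$mode))
  cat(sprintf("  samples: %d, species: %s\n",
              length(unique(x$meta$sample_id)),
              paste(unique(x$meta$species), collapse = ", ")))
  cat(sprintf("  density: %.3f-%.3f g/cm3; sets: %s\n",
              min(x$meta$density), max(x$meta$density),
              paste(names(table(x$meta$set)), table(x$meta$set),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
dim.spectra_dataset <- function(x) dim(x$spectra)

#' Subset the rows of a spectra dataset
#'
#' @param ds a [spectra_dataset()].
#' @param i row index (logical or integer).
#' @return A `spectra_dataset` with the selected rows.
#' @export
subset_rows <- function(ds, i) {
  stopifnot(inherits(ds, "spectra_dataset"))
  out <- ds
  out$spectra <- ds$spectra[i, , drop = FALSE]
  out$meta <- ds$meta[i, , drop = FALSE]
  rownames(out$meta) <- NULL
  out
}

#' Build a 1 nm-spaced wavelength grid
#'
#' @param start,stop grid end points in nm (inclusive).
#' @param step spacing in nm.
#' @return Numeric vector of wavelengths.
#' @examples
#' length(wavelength_grid(350, 2397)) # 2048
#' @export
wavelength_grid <- function(start = 350, stop = 2397, step = 1) {
  if (stop <= start) stop("stop must exceed start")
  if (step <= 0) stop("step must be positive")
  seq(start, stop, by = step)
}

#' Convert reflectance spectra to absorbance
#'
#' Absorbance is taken as log10(1/R), the usual transform applied to
#' reflectance spectra before chemometric modeling.
#'
#' @param ds a reflectance-mode [spectra_dataset()].
#' @return The dataset with spectra replaced by log10(1/R) and mode
#'   flipped to `"absorbance"`.
#' @export
to_absorbance <- function(ds) {
  stopifnot(inherits(ds, "spectra_dataset"))
  if (ds$mode != "reflectance")
    stop("to_absorbance() expects a reflectance-mode dataset")
  if (any(ds$spectra <= 0)) stop("reflectance must be positive")
  ds$spectra <- -log10(ds$spectra)
  ds$mode <- "absorbance"
  ds
}

#' Convert absorbance spectra back to reflectance
#'
#' Inverse of [to_absorbance()]: R = 10^(-A).
#'
#' @param ds an absorbance-mode [spectra_dataset()].
#' @return The dataset in reflectance mode.
#' @export
to_reflectance <- function(ds) {
  stopifnot(inherits(ds, "spectra_dataset"))
  if (ds$mode != "absorbance")
    stop("to_reflectance() expects an absorbance-mode dataset")
  r <- 10^(-ds$spectra)
  r[r > 1] <- 1
  ds$spectra <- r
  ds$mode <- "reflectance"
  ds
}

#' Average replicate scans into one spectrum per sample
#'
#' Several scans are usually collected per specimen and their average is
#' treated as that specimen's raw spectrum. Averaging is done in the
#' dataset's current mode (reflectance by default), before any conversion
#' to absorbance.
#'
#' @param ds a [spectra_dataset()] with replicate rows.
#' @param replicates_per_sample expected number of rows per sample id;
#'   an error lists the offending ids when counts disagree.
#' @return A `spectra_dataset` with one row per sample id; density and
#'   labels are carried through from the first replicate.
#' @export
average_replicates <- function(ds, replicates_per_sample = NULL) {
  stopifnot(inherits(ds, "spectra_dataset"))
  ids <- ds$meta$sample_id
  counts <- table(ids)
  if (is.null(replicates_per_sample)) {
    if (length(unique(counts)) != 1L)
      stop("unequal replicate counts for sample ids: ",
           paste(names(counts)[counts != max(counts)], collapse = ", "))
  } else if (any(counts != replicates_per_sample)) {
    stop("sample ids without exactly ", replicates_per_sample,
         " replicates: ",
         paste(names(counts)[counts != replicates_per_sample], collapse = ", "))
  }
  keep_order <- unique(ids)
  first_row <- match(keep_order, ids)
  avg <- rowsum(ds$spectra, group = ids, reorder = FALSE) /
    as.vector(counts[unique(ids)])
  # rowsum groups in first-appearance order with reorder = FALSE
  out <- ds
  out$spectra <- unname(avg)
  out$meta <- ds$meta[first_row, , drop = FALSE]
  out$meta$replicate <- 1L
  rownames(out$meta) <- NULL
  out
}

#' Split samples into calibration and prediction sets
#'
#' Random sampling, stratified by species so that every species appears in
#' both sets. The number of calibration samples per species is
#' `floor(n * fraction)`, with at least one sample kept for prediction.
#' After splitting, the prediction-set density range is checked against the
#' calibration range; values outside it raise a warning (extrapolation),
#' not an error.
#'
#' @param ds a [spectra_dataset()], one row per sample.
#' @param fraction_calibration fraction of samples assigned to calibration,
#'   in (0, 1).
#' @param seed integer seed making the assignment reproducible.
#' @return The dataset with `set` labels filled in.
#' @export
random_split <- function(ds, fraction_calibration = 0.7, seed = 1L) {
  stopifnot(inherits(ds, "spectra_dataset"))
  if (fraction_calibration <= 0 || fraction_calibration >= 1)
    stop("fraction_calibration must be in (0, 1)")
  set <- rep("prediction", nrow(ds$spectra))
  with_seed(seed, {
    for (sp in unique(ds$meta$species)) {
      rows <- which(ds$meta$species == sp)
      n <- length(rows)
      if (n < 2L)
        stop("species '", sp, "' has fewer than 2 samples; cannot split")
      n_cal <- max(1L, min(n - 1L, floor(n * fraction_calibration)))
      pick <- rows[sample.int(n, n_cal)]
      set[pick] <- "calibration"
    }
  })
  ds$meta$set <- set
  cal <- ds$meta$density[set == "calibration"]
  pred <- ds$meta$density[set == "prediction"]
  if (length(pred) && (min(pred) < min(cal) || max(pred) > max(cal)))
    warning("prediction-set density range extends beyond the calibration set")
  ds
}

#' Descriptive statistics of wood density
#'
#' @param ds a [spectra_dataset()] with set labels assigned.
#' @return A data frame with one row per species x set combination and
#'   columns `species`, `set`, `n`, `min`, `max`, `mean`, `sd`.
#' @export
describe_density <- function(ds) {
  stopifnot(inherits(ds, "spectra_dataset"))
  groups <- split(ds$meta$density,
                  list(species = ds$meta$species, set = ds$meta$set),
                  drop = TRUE)
  keys <- strsplit(names(groups), ".", fixed = TRUE)
  out <- data.frame(
    species = vapply(keys, `[`, "", 1L),
    set = vapply(keys, `[`, "", 2L),
    n = vapply(groups, length, 0L),
    min = vapply(groups, min, 0),
    max = vapply(groups, max, 0),
    mean = vapply(groups, mean, 0),
    sd = vapply(groups, stats::sd, 0),
    stringsAsFactors = FALSE
  )
  out$sd[out$n == 1L] <- 0
  rownames(out) <- NULL
  out[order(out$species, out$set), , drop = FALSE]
}

#' Extract the calibration or prediction partition
#'
#' @param ds a split [spectra_dataset()].
#' @param which `"calibration"` or `"prediction"`.
#' @return A `spectra_dataset` restricted to the requested set.
#' @export
get_set <- function(ds, which = c("calibration", "prediction")) {
  which <- match.arg(which)
  subset_rows(ds, ds$meta$set == which)
}
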