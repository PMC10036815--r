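# Synthetic Vis-NIR wood spectra with known ground truth.
#
# The generative model is the minimal one that every method in the
# package is designed to act on: absorbance is a Beer-Lambert mixture of
# Gaussian component bands (path length fixed at 1), each observed
# spectrum is distorted by per-sample affine scatter (what MSC/SNV
# remove), a low-order polynomial baseline and white noise, and the
# density target is an affine (optionally weakly quadratic) function of
# the component concentrations.

#' Default absorption band library
#'
#' Eight bands at 1157, 1171, 1370, 1597, 1811, 1830, 2200 and 2353 nm,
#' the wood-chemistry wavelengths associated with hemicellulose,
#' cellulose and lignin absorption. Each band carries a Gaussian profile
#' (width = standard deviation in nm) and a loading on one of the three
#' components.
#'
#' @return A data frame with columns `center`, `width`,
#'   `hemicellulose`, `cellulose`, `lignin`.
#' @export
default_band_library <- function() {
  data.frame(
    center = c(1157, 1171, 1370, 1597, 1811, 1830, 2200, 2353),
    width = c(25, 20, 35, 45, 30, 25, 40, 35),
    hemicellulose = c(0.9, 0, 0, 0, 0.7, 0, 0, 0),
    cellulose = c(0, 0.8, 1.0, 0.9, 0, 0, 0, 0.6),
    lignin = c(0, 0, 0, 0, 0, 0.7, 1.0, 0)
  )
}

#' Configuration of the synthetic spectra generator
#'
#' Defaults emulate the measurement setting the package targets: a 1
#' nm-spaced 350-2397 nm grid (2048 variables), three replicate scans per
#' specimen, three chemical components whose concentrations drive both
#' the band amplitudes and a density in roughly 0.6-1.15 g/cm3.
#'
#' @param n_samples number of specimens.
#' @param wavelength_start,wavelength_stop,wavelength_step grid in nm.
#' @param conc_mean,conc_sd per-component concentration mean and spread
#'   (unitless mass fractions); draws are truncated at zero.
#' @param density_intercept,density_slopes affine map from concentrations
#'   to density in g/cm3.
#' @param nonlinearity_strength coefficient of the quadratic term
#'   `(sum of concentrations)^2` added to the density; 0 keeps the
#'   spectra-density relation exactly linear.
#' @param scatter_slope_range,scatter_offset_range per-sample
#'   multiplicative and additive scatter, drawn uniformly.
#' @param baseline_amplitude scale of the per-sample random degree-2
#'   polynomial baseline (absorbance units).
#' @param noise_sd standard deviation of the additive white noise per
#'   replicate (absorbance units).
#' @param replicates_per_sample replicate scans per specimen.
#' @param seed integer seed; equal seeds give identical datasets.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_samples = 120L,
                         wavelength_start = 350, wavelength_stop = 2397,
                         wavelength_step = 1,
                         conc_mean = c(0.30, 0.35, 0.30),
                         conc_sd = c(0.08, 0.08, 0.08),
                         density_intercept = 0.45,
                         density_slopes = c(0.50, 0.45, 0.50),
                         nonlinearity_strength = 0,
                         scatter_slope_range = c(0.95, 1.05),
                         scatter_offset_range = c(-0.02, 0.02),
                         baseline_amplitude = 0.02,
                         noise_sd = 0.005,
                         replicates_per_sample = 3L,
                         seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    wavelength_start = wavelength_start,
    wavelength_stop = wavelength_stop,
    wavelength_step = wavelength_step,
    conc_mean = conc_mean, conc_sd = conc_sd,
    density_intercept = density_intercept,
    density_slopes = density_slopes,
    nonlinearity_strength = nonlinearity_strength,
    scatter_slope_range = scatter_slope_range,
    scatter_offset_range = scatter_offset_range,
    baseline_amplitude = baseline_amplitude,
    noise_sd = noise_sd,
    replicates_per_sample = as.integer(replicates_per_sample),
    seed = as.integer(seed)
  )
  if (cfg$wavelength_stop <= cfg$wavelength_start) stop("stop must exceed start")
  if (cfg$wavelength_step <= 0) stop("step must be positive")
  if (cfg$n_samples < 4L) stop("n_samples must be at least 4")
  if (cfg$replicates_per_sample < 1L) stop("replicates_per_sample must be >= 1")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(cfg$conc_sd) != length(cfg$conc_mean))
    stop("conc_mean and conc_sd lengths differ")
  if (any(cfg$conc_sd < 0) || any(cfg$conc_mean < 0))
    stop("concentration parameters must be >= 0")
  if (length(cfg$density_slopes) != length(cfg$conc_mean))
    stop("density_slopes must match the number of components")
  class(cfg) <- "synth_config"
  cfg
}

#' Draw component concentrations
#'
#' Concentrations are normal draws truncated at zero, one column per
#' component, reproducible under the config seed.
#'
#' @param config a [synth_config()].
#' @return An `n_samples` x `n_components` matrix.
#' @export
simulate_concentrations <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  K <- length(config$conc_mean)
  with_seed(config$seed, {
    m <- matrix(stats::rnorm(config$n_samples * K), ncol = K)
    m <- sweep(m, 2L, config$conc_sd, `*`)
    m <- sweep(m, 2L, config$conc_mean, `+`)
    pmax(m, 0)
  })
}

#' Map concentrations to wood density
#'
#' density = intercept + sum_k slope_k c_k
#'   + nonlinearity_strength * (sum_k c_k)^2, in g/cm3.
#'
#' @param concentrations samples x components matrix.
#' @param config a [synth_config()].
#' @return Numeric density vector.
#' @export
density_from_concentrations <- function(concentrations, config) {
  stopifnot(inherits(config, "synth_config"))
  concentrations <- as.matrix(concentrations)
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  lin <- config$density_intercept +
    as.vector(concentrations %*% config$density_slopes)
  lin + config$nonlinearity_strength * rowSums(concentrations)^2
}

#' Simulate reflectance spectra from concentrations
#'
#' Clean absorbance is the Beer-Lambert band mixture
#' `A(lambda) = sum_bands Gaussian(lambda; center, width) * (loadings . c)`.
#' The observed absorbance of sample i is
#' `slope_i * A + offset_i + baseline_i(lambda)` plus white noise per
#' replicate; scatter and baseline are drawn per sample so replicates
#' share everything but the noise. Reflectance is `10^(-observed)`,
#' clipped to `[1e-6, 1]` so `log10(1/R)` is always defined.
#'
#' @param concentrations samples x components matrix.
#' @param bands band library as from [default_band_library()].
#' @param config a [synth_config()].
#' @return List with `reflectance` (replicate-level matrix, samples
#'   blocked in order), `truth` (list: `concentrations`, `clean_spectra`,
#'   `informative_band_indices`) and `wavelengths`.
#' @export
simulate_spectra <- function(concentrations, bands, config) {
  stopifnot(inherits(config, "synth_config"))
  wl <- wavelength_grid(config$wavelength_start, config$wavelength_stop,
                        config$wavelength_step)
  p <- length(wl)
  n <- nrow(concentrations)
  comp_cols <- setdiff(names(bands), c("center", "width"))
  L <- as.matrix(bands[, comp_cols, drop = FALSE])   # bands x components
  if (ncol(L) != ncol(concentrations))
    stop("band loadings and concentration columns disagree")
  profile <- sapply(seq_len(nrow(bands)), function(b)
    exp(-((wl - bands$center[b])^2) / (2 * bands$width[b]^2)))  # p x bands
  amplitude <- concentrations %*% t(L)               # n x bands
  clean <- amplitude %*% t(profile)                  # n x p
  u <- (wl - min(wl)) / (max(wl) - min(wl))
  reps <- config$replicates_per_sample
  with_seed(config$seed + 1L, {
    slope <- stats::runif(n, config$scatter_slope_range[1],
                          config$scatter_slope_range[2])
    offset <- stats::runif(n, config$scatter_offset_range[1],
                           config$scatter_offset_range[2])
    bl_coef <- matrix(stats::runif(3L * n, -1, 1), ncol = 3L)
    baseline <- config$baseline_amplitude *
      (bl_coef %*% rbind(rep(1, p), u, u^2))         # n x p
    observed <- slope * clean + offset + baseline
    out <- matrix(0, nrow = n * reps, ncol = p)
    for (r in seq_len(reps)) {
      noise <- if (config$noise_sd > 0)
        matrix(stats::rnorm(n * p, sd = config$noise_sd), nrow = n)
      else 0
      out[seq(r, n * reps, by = reps), ] <- observed + noise
    }
    reflectance <- pmin(pmax(10^(-out), 1e-6), 1)
    inside <- rep(FALSE, p)
    for (b in seq_len(nrow(bands)))
      inside <- inside | abs(wl - bands$center[b]) <= 2 * bands$width[b]
    list(
      reflectance = reflectance,
      wavelengths = wl,
      truth = list(
        concentrations = concentrations,
        clean_spectra = clean,
        informative_band_indices = which(inside)
      )
    )
  })
}

#' Generate a complete synthetic dataset
#'
#' Glue over the three generators: concentrations, densities, spectra.
#' Returns replicate-level reflectance spectra as a [spectra_dataset()]
#' (species and location set to `"synthetic"`) plus the ground truth used
#' by recovery tests.
#'
#' @param config a [synth_config()].
#' @param bands band library; defaults to [default_band_library()].
#' @return List with elements `dataset` and `truth`.
#' @examples
#' d <- generate_dataset(synth_config(n_samples = 10, wavelength_stop = 605,
#'                                    replicates_per_sample = 3))
#' dim(d$dataset) # 30 spectra
#' @export
generate_dataset <- function(config = synth_config(), bands = default_band_library()) {
  stopifnot(inherits(config, "synth_config"))
  conc <- simulate_concentrations(config)
  density <- density_from_concentrations(conc, config)
  sim <- simulate_spectra(conc, bands, config)
  reps <- config$replicates_per_sample
  n <- config$n_samples
  ds <- spectra_dataset(
    wavelengths = sim$wavelengths,
    spectra = sim$reflectance,
    density = rep(density, each = reps),
    sample_id = sprintf("S%03d", rep(seq_len(n), each = reps)),
    species = "synthetic", location = "synthetic",
    replicate = rep(seq_len(reps), times = n),
    mode = "reflectance"
  )
  list(dataset = ds, truth = sim$truth)
}
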