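test_that("default band library covers the eight reference wavelengths", {
  bands <- default_band_library()
  expect_setequal(bands$center,
                  c(1157, 1171, 1370, 1597, 1811, 1830, 2200, 2353))
  expect_equal(nrow(bands), 8L)
  expect_true(all(bands$center >= 350 & bands$center <= 2397))
  expect_true(all(bands$width >= 20 & bands$width <= 60))
  loadings <- as.matrix(bands[, c("hemicellulose", "cellulose", "lignin")])
  expect_true(all(rowSums(loadings > 0) >= 1))
  expect_true(2200 %in% bands$center)
})

test_that("concentration draws are reproducible, nonnegative and centered", {
  cfg <- small_config()
  c1 <- simulate_concentrations(cfg)
  c2 <- simulate_concentrations(cfg)
  expect_identical(c1, c2)
  expect_true(all(c1 >= 0))

  cfg0 <- small_config(conc_sd = c(0, 0, 0))
  c0 <- simulate_concentrations(cfg0)
  expect_true(all(abs(sweep(c0, 2L, cfg0$conc_mean)) < 1e-12))

  big <- synth_config(n_samples = 10000L, conc_mean = c(0.4, 0.4, 0.4),
                      wavelength_stop = 500, seed = 7L)
  cb <- simulate_concentrations(big)
  expect_true(all(abs(colMeans(cb) - 0.4) < 0.01))
})

test_that("density map follows the affine-plus-quadratic form", {
  cfg <- synth_config(n_samples = 4, conc_mean = 0.3, conc_sd = 0.1,
                      density_intercept = 0.5, density_slopes = 1,
                      nonlinearity_strength = 0, wavelength_stop = 500)
  expect_equal(density_from_concentrations(matrix(0.2), cfg), 0.7)

  cfg2 <- synth_config(n_samples = 4, conc_mean = c(0.2, 0.2),
                       conc_sd = c(0.1, 0.1), density_intercept = 0,
                       density_slopes = c(1, 1),
                       nonlinearity_strength = 0.5, wavelength_stop = 500)
  # linear part 0.4, quadratic adds 0.5 * 0.4^2 = 0.08
  expect_equal(density_from_concentrations(matrix(c(0.1, 0.3), 1), cfg2),
               0.4 + 0.08)

  # default configuration brackets the realistic density range
  cfg500 <- synth_config(n_samples = 500L, wavelength_stop = 500, seed = 1L)
  dens <- density_from_concentrations(simulate_concentrations(cfg500), cfg500)
  expect_true(min(dens) >= 0.50 && max(dens) <= 1.20)
})

test_that("spectra follow the band mixture with scatter and noise layers", {
  bands <- default_band_library()

  # degenerate scatter and zero noise reproduce the clean absorbance
  cfg <- small_config(noise_sd = 0, scatter_slope_range = c(1, 1),
                      scatter_offset_range = c(0, 0),
                      baseline_amplitude = 0, replicates_per_sample = 1L)
  conc <- simulate_concentrations(cfg)
  sim <- simulate_spectra(conc, bands, cfg)
  observed_abs <- -log10(sim$reflectance)
  expect_lt(max(abs(observed_abs - sim$truth$clean_spectra)), 1e-9)

  # a single band peaks at its center
  one_band <- data.frame(center = 1370, width = 30, cellulose = 1)
  cfg1 <- synth_config(n_samples = 4, conc_mean = 1, conc_sd = 0,
                       noise_sd = 0, scatter_slope_range = c(1, 1),
                       scatter_offset_range = c(0, 0), baseline_amplitude = 0,
                       density_slopes = 0.3, replicates_per_sample = 1L)
  sim1 <- simulate_spectra(matrix(1, 4, 1), one_band, cfg1)
  peak <- sim1$wavelengths[which.max(sim1$truth$clean_spectra[1, ])]
  expect_equal(peak, 1370)

  # default grid gives 2048 wavelengths
  cfg_full <- synth_config(n_samples = 4)
  sim_full <- simulate_spectra(simulate_concentrations(cfg_full), bands, cfg_full)
  expect_equal(ncol(sim_full$reflectance), 2048L)
})

test_that("clean absorbance is local to the band windows", {
  bands <- default_band_library()
  cfg <- small_config(noise_sd = 0, baseline_amplitude = 0,
                      replicates_per_sample = 1L)
  sim <- simulate_spectra(simulate_concentrations(cfg), bands, cfg)
  wl <- sim$wavelengths
  far <- rep(TRUE, length(wl))
  for (b in seq_len(nrow(bands)))
    far <- far & abs(wl - bands$center[b]) > 8 * bands$width[b]
  expect_true(any(far))
  expect_lt(max(abs(sim$truth$clean_spectra[, far])), 1e-12)
})

test_that("generate_dataset assembles replicate-level data deterministically", {
  cfg <- small_config(n_samples = 30L)
  d1 <- generate_dataset(cfg)
  expect_equal(nrow(d1$dataset$spectra), 90L)
  expect_equal(unique(d1$dataset$meta$species), "synthetic")
  expect_true(all(d1$truth$informative_band_indices %in%
                    seq_along(d1$dataset$wavelengths)))

  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_spectra(d1$dataset, f1)
  write_spectra(generate_dataset(cfg)$dataset, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("noise-free linear density is exactly recoverable by PLS", {
  cfg <- small_config(noise_sd = 0, nonlinearity_strength = 0,
                      scatter_slope_range = c(1, 1),
                      scatter_offset_range = c(0, 0),
                      baseline_amplitude = 0,
                      replicates_per_sample = 1L)
  d <- generate_dataset(cfg)
  ab <- to_absorbance(d$dataset)
  fit <- pls_fit(ab$spectra, ab$meta$density, 10)
  m <- compute_metrics(ab$meta$density, predict(fit, ab$spectra))
  expect_gt(m$r2, 0.999)
})
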