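test_that("spectra tables round-trip through delimited text", {
  cfg <- small_config(n_samples = 5L, replicates_per_sample = 1L)
  ds <- generate_dataset(cfg)$dataset
  f <- tempfile(fileext = ".csv")
  write_spectra(ds, f)
  back <- read_spectra(f)
  expect_equal(back$wavelengths, ds$wavelengths)
  expect_lt(max(abs(back$spectra - ds$spectra)), 1e-12)
  expect_equal(back$meta$density, ds$meta$density)
  expect_equal(back$mode, ds$mode)
  unlink(f)
})

test_that("a full-width 2048-column header is accepted", {
  wl <- wavelength_grid(350, 2397)
  expect_length(wl, 2048L)
  ds <- spectra_dataset(wl, matrix(0.5, 2, 2048), density = c(0.6, 0.7),
                        sample_id = c("a", "b"))
  f <- tempfile(fileext = ".csv")
  write_spectra(ds, f)
  expect_equal(ncol(read_spectra(f)$spectra), 2048L)
  unlink(f)
})

test_that("malformed tables are rejected with informative errors", {
  wl <- c(400, 401, 402)
  ds <- spectra_dataset(wl, matrix(0.5, 2, 3), density = c(0.6, 0.7),
                        sample_id = c("a", "b"))
  f <- tempfile(fileext = ".csv")
  write_spectra(ds, f)
  lines <- readLines(f)

  bad <- lines
  bad[3] <- sub(",0\\.5$", ",oops", bad[3])   # corrupt a spectral cell
  writeLines(bad, f)
  expect_error(read_spectra(f), "row")

  dup <- lines
  dup[4] <- lines[3]
  writeLines(dup, f)
  expect_error(read_spectra(f), "duplicate")

  swapped <- lines
  swapped[2] <- sub("401", "399", swapped[2])
  writeLines(swapped, f)
  expect_error(read_spectra(f), "increasing")
  unlink(f)
})

test_that("replicate averaging takes per-wavelength means and checks counts", {
  wl <- c(400, 401)
  sp <- rbind(c(0.2, 0.2), c(0.4, 0.4), c(0.6, 0.6),
              c(0.3, 0.3), c(0.3, 0.3), c(0.3, 0.3))
  ds <- spectra_dataset(wl, sp, density = rep(c(0.6, 0.8), each = 3),
                        sample_id = rep(c("a", "b"), each = 3),
                        replicate = rep(1:3, 2))
  avg <- average_replicates(ds, 3L)
  expect_equal(nrow(avg$spectra), 2L)
  expect_equal(avg$spectra[1, 1], 0.4)
  expect_equal(avg$spectra[2, ], c(0.3, 0.3))  # identical replicates
  expect_equal(avg$meta$density, c(0.6, 0.8))

  ds_bad <- subset_rows(ds, 1:5)
  expect_error(average_replicates(ds_bad, 3L), "b")

  d90 <- generate_dataset(small_config(n_samples = 30L))$dataset
  expect_equal(nrow(average_replicates(d90, 3L)$spectra), 30L)
})

test_that("absorbance conversion is log10(1/R) with an exact inverse", {
  wl <- c(400, 401)
  ds <- spectra_dataset(wl, rbind(c(0.1, 1)), density = 0.6)
  ab <- to_absorbance(ds)
  expect_equal(ab$spectra[1, ], c(1, 0))
  expect_equal(ab$mode, "absorbance")
  back <- to_reflectance(ab)
  expect_lt(max(abs(back$spectra - ds$spectra)), 1e-12)
  expect_error(to_absorbance(ab), "reflectance")
})

test_that("averaging reflectance does not commute with absorbance in general", {
  wl <- c(400, 401)
  sp <- rbind(c(0.2, 0.5), c(0.8, 0.5))
  ds <- spectra_dataset(wl, sp, density = c(0.6, 0.6),
                        sample_id = c("a", "a"), replicate = 1:2)
  avg_then_abs <- to_absorbance(average_replicates(ds, 2L))$spectra[1, 1]
  abs_then_avg <- mean(-log10(sp[, 1]))
  expect_gt(abs(avg_then_abs - abs_then_avg), 1e-3)
  # but they agree when replicates are identical
  expect_equal(to_absorbance(average_replicates(ds, 2L))$spectra[1, 2],
               -log10(0.5))
})

test_that("random splitting is stratified, reproducible and exhaustive", {
  cfg <- small_config(n_samples = 30L, replicates_per_sample = 1L)
  ds <- generate_dataset(cfg)$dataset
  s1 <- suppressWarnings(random_split(ds, 0.7, seed = 4L))
  expect_equal(sum(s1$meta$set == "calibration"), 21L)
  expect_equal(sum(s1$meta$set == "prediction"), 9L)
  s2 <- suppressWarnings(random_split(ds, 0.7, seed = 4L))
  expect_identical(s1$meta$set, s2$meta$set)
  expect_true(all(s1$meta$set %in% c("calibration", "prediction")))

  # a prediction density outside the calibration range triggers a warning
  wl <- c(400, 401)
  tiny <- spectra_dataset(wl, matrix(0.5, 4, 2),
                          density = c(0.6, 0.7, 0.8, 2.0),
                          sample_id = letters[1:4])
  got_warning <- FALSE
  for (s in 1:20) {
    w <- tryCatch({ random_split(tiny, 0.7, seed = s); NULL },
                  warning = function(w) w)
    if (!is.null(w)) { got_warning <- TRUE; break }
  }
  expect_true(got_warning)

  lone <- spectra_dataset(wl, matrix(0.5, 3, 2), density = c(0.6, 0.7, 0.8),
                          sample_id = letters[1:3],
                          species = c("a", "a", "b"))
  expect_error(random_split(lone, 0.7, seed = 1L), "fewer than 2")
})

test_that("density description reports the five statistics per group", {
  wl <- c(400, 401)
  ds <- spectra_dataset(wl, matrix(0.5, 6, 2),
                        density = c(0.6, 0.6, 0.6, 0.7, 0.8, 0.9),
                        sample_id = letters[1:6],
                        species = rep(c("x", "y"), each = 3),
                        set = rep(c("calibration", "prediction"), 3))
  tab <- describe_density(ds)
  expect_setequal(names(tab), c("species", "set", "n", "min", "max", "mean", "sd"))
  expect_equal(nrow(tab), 4L)  # two species x two sets
  const <- tab[tab$species == "x" & tab$set == "calibration", ]
  expect_equal(const$sd, 0)

  d500 <- generate_dataset(synth_config(n_samples = 500L,
                                        wavelength_stop = 500, seed = 1L))
  dd <- describe_density(d500$dataset)
  expect_true(all(dd$min >= 0.50) && all(dd$max <= 1.20))
})
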