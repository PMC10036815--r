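# Shared fixtures, all generated in code.

# small synthetic dataset: n samples, 256-point grid (350..2390 nm, 8 nm
# step) so the eight default bands all fall inside the grid
small_config <- function(n_samples = 40L, noise_sd = 0.005, seed = 1L, ...) {
  synth_config(n_samples = n_samples, wavelength_start = 350,
               wavelength_stop = 2390, wavelength_step = 8,
               noise_sd = noise_sd, seed = seed, ...)
}

# tiny regression problem with a known sparse truth: y depends on a few
# informative columns of smooth correlated predictors
make_sparse_problem <- function(n = 40L, p = 20L, informative = c(5L),
                                noise_sd = 0, seed = 3L) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    X <- matrix(rnorm(n * p), n, p)
    y <- rowSums(X[, informative, drop = FALSE])
    if (noise_sd > 0) y <- y + rnorm(n, sd = noise_sd)
    list(X = X, y = y)
  })
}

# fraction of selected indices that fall inside the planted band windows
in_band_fraction <- function(selected, truth) {
  mean(selected %in% truth$informative_band_indices)
}
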