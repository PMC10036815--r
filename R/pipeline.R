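# Orchestration of the full chemometric comparison: denoising parameter
# search, wavelength-selection comparison, linear and tuned nonlinear
# calibration, and the signal-vs-combined model contrast.

#' Workflow configuration
#'
#' Bundles every knob of [run_single_species()] and [run_combined()].
#' The defaults mirror the package-wide conventions; the `light` preset
#' shrinks the optimizer budgets for quick desk-scale runs.
#'
#' @param split_fraction calibration fraction of [random_split()].
#' @param seed global seed; stage seeds are derived from it.
#' @param candidate_functions stage-1 wavelet candidates.
#' @param order_range,level_range wavelet search scans.
#' @param selectors subset of `c("spa", "uve", "cars", "iriv")`.
#' @param models subset of `c("pls", "pcr", "foa_grnn", "rsm_pso_svm")`
#'   fitted on the winning wavelength subset.
#' @param n_folds cross-validation folds for PLS scoring.
#' @param max_latent cap of the latent-variable scan.
#' @param iriv_downsample keep every k-th wavelength for IRIV when the
#'   grid exceeds 512 variables (1 disables); IRIV's binary sampling is
#'   otherwise prohibitively slow on full grids.
#' @param cars_runs,iriv_rows,spa_max_vars selector budgets.
#' @param foa_iterations,foa_flies FOA budget.
#' @param pso a [pso_config()] used as the PSO-SVR base configuration.
#' @param light logical; shrink every budget for smoke-scale runs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(split_fraction = 0.7, seed = 1L,
                       candidate_functions = c("haar", "db3", "sym3", "bior1.3"),
                       order_range = 2:8, level_range = 1:8,
                       selectors = c("spa", "uve", "cars", "iriv"),
                       models = c("pls", "foa_grnn", "rsm_pso_svm"),
                       n_folds = 5L, max_latent = 10L,
                       iriv_downsample = 4L,
                       cars_runs = 50L, iriv_rows = 100L, spa_max_vars = 30L,
                       foa_iterations = 40L, foa_flies = 10L,
                       pso = pso_config(population = 10L, max_generation = 15L,
                                        n_cv = 5L),
                       light = FALSE) {
  cfg <- list(split_fraction = split_fraction, seed = as.integer(seed),
              candidate_functions = candidate_functions,
              order_range = order_range, level_range = level_range,
              selectors = selectors, models = models,
              n_folds = as.integer(n_folds), max_latent = as.integer(max_latent),
              iriv_downsample = as.integer(iriv_downsample),
              cars_runs = as.integer(cars_runs),
              iriv_rows = as.integer(iriv_rows),
              spa_max_vars = as.integer(spa_max_vars),
              foa_iterations = as.integer(foa_iterations),
              foa_flies = as.integer(foa_flies), pso = pso)
  if (light) {
    cfg$order_range <- 3L
    cfg$level_range <- c(2L, 4L)
    cfg$cars_runs <- 25L
    cfg$iriv_rows <- 50L
    cfg$foa_iterations <- 15L
    cfg$foa_flies <- 6L
    cfg$pso <- pso_config(population = 6L, max_generation = 8L, n_cv = 3L)
    # the Box-Behnken PSO-SVR sweep is orders of magnitude heavier than
    # everything else; smoke-scale runs keep the linear + GRNN pair
    cfg$models <- intersect(cfg$models, c("pls", "pcr", "foa_grnn"))
    if (!length(cfg$models)) cfg$models <- c("pls", "foa_grnn")
  }
  if (!length(cfg$models)) stop("at least one model is required")
  class(cfg) <- "run_config"
  cfg
}

# PLS metrics (calibration + cross-validation) for one variable subset
pls_table_row <- function(Xc, yc, cols, label, n_vars_total, n_folds, seed,
                          max_latent) {
  Xs <- Xc[, cols, drop = FALSE]
  sel <- select_n_latent(Xs, yc, max_latent = max_latent,
                         n_folds = n_folds, seed = seed)
  fit <- pls_fit(Xs, yc, sel$n_latent)
  cal <- compute_metrics(yc, stats::predict(fit, Xs))
  cv <- cross_validate(function(Xt, yt)
    pls_fit(Xt, yt, min(sel$n_latent, ncol(Xt), nrow(Xt) - 1L)),
    Xs, yc, n_folds = n_folds, seed = seed)
  cvm <- compute_metrics(yc, cv$predictions)
  data.frame(method = label, n_variables = length(cols),
             reduction_pct = reduction_percent(length(cols), n_vars_total),
             n_latent = sel$n_latent,
             r2_cal = cal$r2, rmse_cal = cal$rmse, rpd_cal = cal$rpd,
             rsd_cal = cal$rsd,
             r2_cv = cvm$r2, rmse_cv = cvm$rmse, rpd_cv = cvm$rpd,
             rsd_cv = cvm$rsd, rmsecv = cv$rmsecv)
}

run_one_species <- function(ds, config) {
  seed <- config$seed
  avg <- average_replicates(ds)
  ab <- to_absorbance(avg)
  ab <- random_split(ab, config$split_fraction, seed = seed)
  cal <- get_set(ab, "calibration")
  pred <- get_set(ab, "prediction")

  # stage A: wavelet-parameter search on the calibration set
  search <- select_wavelet_params(
    cal, candidate_functions = config$candidate_functions,
    order_range = config$order_range, level_range = config$level_range,
    n_folds = config$n_folds, seed = seed, max_latent = config$max_latent)
  wspec <- search$spec

  cal_d <- lwt_denoise(cal, wspec)
  pred_d <- lwt_denoise(pred, wspec)
  Xc <- cal_d$spectra
  yc <- cal_d$meta$density
  p <- ncol(Xc)

  # stage B: wavelength-selection comparison on denoised spectra
  rows <- list(
    pls_table_row(cal$spectra, yc, seq_len(p), "full_pls", p,
                  config$n_folds, seed, config$max_latent),
    pls_table_row(Xc, yc, seq_len(p), "lwt_pls", p,
                  config$n_folds, seed, config$max_latent)
  )
  selections <- list()
  for (m in config$selectors) {
    res <- switch(m,
      spa = {
        nc <- nrow(Xc)
        rank_cap <- nc - max(2L, round(0.25 * nc)) - 1L
        mv <- min(config$spa_max_vars, rank_cap, p)
        spa(Xc, yc, min_vars = min(5L, mv), max_vars = mv, seed = seed)
      },
      uve = uve(Xc, yc, n_latent = config$max_latent, seed = seed),
      cars = cars(Xc, yc, n_runs = config$cars_runs,
                  n_latent = config$max_latent, n_cv = config$n_folds,
                  seed = seed),
      iriv = {
        keep <- if (p > 512L && config$iriv_downsample > 1L)
          seq(1L, p, by = config$iriv_downsample) else seq_len(p)
        r <- iriv(Xc[, keep, drop = FALSE], yc,
                  n_rows_bms = max(50L, config$iriv_rows),
                  n_latent = config$max_latent, n_cv = config$n_folds,
                  seed = seed)
        r$selected <- keep[r$selected]
        r
      },
      stop("unknown selector: ", m))
    selections[[m]] <- res
    rows[[length(rows) + 1L]] <-
      pls_table_row(Xc, yc, res$selected, paste0(m, "_pls"), p,
                    config$n_folds, seed, config$max_latent)
  }
  selection_table <- do.call(rbind, rows)

  # stage C: winning subset = lowest PLS RMSECV among the selectors
  sel_rows <- selection_table[!selection_table$method %in%
                                c("full_pls", "lwt_pls"), , drop = FALSE]
  if (nrow(sel_rows)) {
    best_m <- sub("_pls$", "", sel_rows$method[which.min(sel_rows$rmsecv)])
    best_cols <- selections[[best_m]]$selected
  } else {
    best_m <- "none"
    best_cols <- seq_len(p)
  }

  # stage D: calibration models on the winning subset, evaluated on the
  # prediction set with raw and with denoised spectra
  model_rows <- list()
  eval_model <- function(model, label) {
    fitted <- stats::predict(model, Xc[, best_cols, drop = FALSE])
    calm <- compute_metrics(yc, fitted)
    for (prep in c("raw", "lwt")) {
      Xp <- if (prep == "raw") pred$spectra else pred_d$spectra
      pm <- compute_metrics(pred$meta$density,
                            stats::predict(model, Xp[, best_cols, drop = FALSE]))
      model_rows[[length(model_rows) + 1L]] <<- data.frame(
        model = label, prediction_spectra = prep, selector = best_m,
        n_variables = length(best_cols),
        r2_cal = calm$r2, rmse_cal = calm$rmse, rpd_cal = calm$rpd,
        rsd_cal = calm$rsd,
        r2_pred = pm$r2, rmse_pred = pm$rmse, rpd_pred = pm$rpd,
        rsd_pred = pm$rsd)
    }
  }
  Xsub <- Xc[, best_cols, drop = FALSE]
  for (mod in config$models) {
    if (mod == "pls") {
      nl <- select_n_latent(Xsub, yc, max_latent = config$max_latent,
                            n_folds = config$n_folds, seed = seed)$n_latent
      eval_model(pls_fit(Xsub, yc, nl), "pls")
    } else if (mod == "pcr") {
      nl <- min(config$max_latent, ncol(Xsub), nrow(Xsub) - 1L)
      eval_model(pcr_fit(Xsub, yc, nl), "pcr")
    } else if (mod == "foa_grnn") {
      tr <- foa_grnn_train(Xsub, yc, n_cv = config$n_folds,
                           n_flies = config$foa_flies,
                           n_iterations = config$foa_iterations, seed = seed)
      eval_model(tr$model, "foa_grnn")
    } else if (mod == "rsm_pso_svm") {
      cfg <- config$pso
      cfg$seed <- seed
      tr <- rsm_pso_svm_train(Xsub, yc, pso_base_config = cfg)
      eval_model(tr$model, "rsm_pso_svm")
    } else stop("unknown model: ", mod)
  }

  list(wavelet_spec = wspec, wavelet_table = search$score_table,
       selection_table = selection_table, selections = selections,
       best_selector = best_m, selected = best_cols,
       model_table = do.call(rbind, model_rows),
       split = ab)
}

#' Run the single-species workflow
#'
#' Per species: replicate averaging, absorbance conversion, stratified
#' split, sequential wavelet-parameter search, LWT denoising, comparison
#' of the wavelength selectors by PLS, then the configured calibration
#' models on the winning subset, with prediction-set metrics for both
#' raw and denoised prediction spectra. A failing species is reported
#' and skipped; the other species continue.
#'
#' @param ds a replicate-level [spectra_dataset()].
#' @param config a [run_config()].
#' @return A named list (one element per species) of result bundles:
#'   `wavelet_spec`, `wavelet_table`, `selection_table`, `model_table`,
#'   `best_selector`, `selected`, `split`.
#' @export
run_single_species <- function(ds, config = run_config()) {
  stopifnot(inherits(ds, "spectra_dataset"), inherits(config, "run_config"))
  out <- list()
  for (sp in unique(ds$meta$species)) {
    branch <- subset_rows(ds, ds$meta$species == sp)
    res <- tryCatch(run_one_species(branch, config), error = function(e) {
      warning("species '", sp, "' failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) out[[sp]] <- res
  }
  if (!length(out)) stop("every species branch failed")
  out
}

#' Compare signal and combined linear models
#'
#' Fits PLS and PCR on raw absorbance spectra for each grouping: every
#' single group ("signal" models, one per species x location), each
#' location pooled across species, each species pooled across locations
#' (when present in several), and the all-pooled "combined" model.
#' Calibration, cross-validation and prediction metrics are reported
#' side by side; groups with fewer than `min_samples` samples are
#' skipped with a warning.
#'
#' @param ds a replicate-level [spectra_dataset()].
#' @param config a [run_config()].
#' @param min_samples minimum group size.
#' @return A data frame with one row per grouping x model x metric set.
#' @export
run_combined <- function(ds, config = run_config(), min_samples = 8L) {
  stopifnot(inherits(ds, "spectra_dataset"))
  avg <- average_replicates(ds)
  ab <- to_absorbance(avg)
  key_species <- ab$meta$species
  key_location <- ab$meta$location
  groups <- list()
  for (sp in unique(key_species)) for (loc in unique(key_location[key_species == sp]))
    groups[[paste0("signal:", sp, "@", loc)]] <-
      which(key_species == sp & key_location == loc)
  for (loc in unique(key_location))
    if (length(unique(key_species[key_location == loc])) > 1L)
      groups[[paste0("location:", loc)]] <- which(key_location == loc)
  for (sp in unique(key_species))
    if (length(unique(key_location[key_species == sp])) > 1L)
      groups[[paste0("species:", sp)]] <- which(key_species == sp)
  if (length(unique(paste(key_species, key_location))) > 1L)
    groups[["combined:all"]] <- seq_along(key_species)

  rows <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    if (length(idx) < min_samples) {
      warning("group '", g, "' has fewer than ", min_samples,
              " samples; skipped")
      next
    }
    grp <- subset_rows(ab, idx)
    grp$meta$species <- "pooled"      # single stratum for the split
    grp <- random_split(grp, config$split_fraction, seed = config$seed)
    Xc <- get_set(grp, "calibration")$spectra
    yc <- get_set(grp, "calibration")$meta$density
    Xp <- get_set(grp, "prediction")$spectra
    yp <- get_set(grp, "prediction")$meta$density
    nl <- select_n_latent(Xc, yc, max_latent = config$max_latent,
                          n_folds = config$n_folds, seed = config$seed)$n_latent
    for (mod in c("pls", "pcr")) {
      fit <- if (mod == "pls") pls_fit(Xc, yc, nl)
        else pcr_fit(Xc, yc, min(config$max_latent, ncol(Xc), nrow(Xc) - 1L))
      calm <- compute_metrics(yc, stats::predict(fit, Xc))
      cv <- cross_validate(function(Xt, yt) {
        if (mod == "pls") pls_fit(Xt, yt, min(nl, ncol(Xt), nrow(Xt) - 1L))
        else pcr_fit(Xt, yt, min(config$max_latent, ncol(Xt), nrow(Xt) - 1L))
      }, Xc, yc, n_folds = config$n_folds, seed = config$seed)
      cvm <- compute_metrics(yc, cv$predictions)
      pm <- compute_metrics(yp, stats::predict(fit, Xp))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, model = mod, n_calibration = length(yc),
        n_prediction = length(yp),
        r2_cal = calm$r2, rmse_cal = calm$rmse, rpd_cal = calm$rpd,
        rsd_cal = calm$rsd,
        r2_cv = cvm$r2, rmse_cv = cvm$rmse, rpd_cv = cvm$rpd, rsd_cv = cvm$rsd,
        r2_pred = pm$r2, rmse_pred = pm$rmse, rpd_pred = pm$rpd,
        rsd_pred = pm$rsd)
    }
  }
  if (!length(rows)) stop("no group large enough to model")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
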