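# Sequential wavelet-parameter search for denoising, scored by
# cross-validated PLS on the denoised spectra.

score_denoised <- function(ds, spec, n_folds, seed, max_latent) {
  den <- lwt_denoise(ds, spec)
  X <- den$spectra
  y <- den$meta$density
  sel <- select_n_latent(X, y, max_latent = max_latent,
                         n_folds = n_folds, seed = seed)
  cv <- cross_validate(function(Xt, yt)
    pls_fit(Xt, yt, min(sel$n_latent, ncol(Xt), nrow(Xt) - 1L)),
    X, y, n_folds = n_folds, seed = seed)
  met <- compute_metrics(y, cv$predictions)
  list(rmsecv = cv$rmsecv, r2 = met$r2, rpd = met$rpd, rsd = met$rsd,
       n_latent = sel$n_latent)
}

#' Sequential search for the wavelet denoising parameters
#'
#' Greedy three-stage search mirroring common chemometric practice:
#' stage 1 fixes order = 3, level = 8 and compares the candidate wavelet
#' functions (default haar, db3, sym3, bior1.3) by cross-validated PLS
#' RMSECV on the denoised spectra; stage 2 scans the order for the
#' winning family (db/sym: 2..8; bior: the registered 1.Nd members with
#' Nd in 1, 3, 5; haar has a single member); stage 3 scans the
#' decomposition level 1..8. Ties keep the earlier candidate, so on
#' noise-free data where all candidates score identically the first
#' candidate wins.
#'
#' @param ds a [spectra_dataset()] with density values (typically the
#'   calibration set, absorbance mode).
#' @param candidate_functions character vector of stage-1 wavelet names.
#' @param order_range orders scanned in stage 2 (intersected with the
#'   registered members of the winning family).
#' @param level_range levels scanned in stage 3.
#' @param n_folds,seed cross-validation controls for the PLS scorer.
#' @param max_latent cap on the PLS latent-variable scan.
#' @param threshold_rule,threshold_scale passed to [wavelet_spec()].
#' @return List with `spec` (the winning [wavelet_spec()]) and
#'   `score_table` (one row per evaluated candidate across all stages).
#' @export
select_wavelet_params <- function(ds,
                                  candidate_functions = c("haar", "db3",
                                                          "sym3", "bior1.3"),
                                  order_range = 2:8, level_range = 1:8,
                                  n_folds = 5L, seed = 1L, max_latent = 10L,
                                  threshold_rule = "soft",
                                  threshold_scale = 1) {
  stopifnot(inherits(ds, "spectra_dataset"))
  if (!length(candidate_functions)) stop("empty candidate set")
  bad <- setdiff(candidate_functions, registered_wavelets())
  if (length(bad)) stop("unregistered wavelet(s): ", paste(bad, collapse = ", "))

  # first index within numerical tolerance of the minimum, so exact ties
  # (and round-off-level differences) resolve to the earlier candidate
  pick_min <- function(x) which(x <= min(x) + 1e-10 * max(min(x), 1))[1]

  rows <- list()
  note <- function(stage, name, level, sc) {
    rows[[length(rows) + 1L]] <<- data.frame(
      stage = stage, wavelet = name, level = level,
      rmsecv = sc$rmsecv, r2 = sc$r2, rpd = sc$rpd, rsd = sc$rsd,
      n_latent = sc$n_latent)
  }
  spec_for <- function(name, level) {
    fam <- if (name == "haar") "haar"
      else if (startsWith(name, "bior")) "bior"
      else if (startsWith(name, "db")) "db" else "sym"
    ord <- if (fam == "haar") 1L
      else if (fam == "bior") as.integer(sub("bior1\\.", "", name))
      else as.integer(sub("^(db|sym)", "", name))
    wavelet_spec(fam, ord, level = level, threshold_rule = threshold_rule,
                 threshold_scale = threshold_scale)
  }

  # stage 1: wavelet function at order 3, level 8
  stage1 <- vapply(candidate_functions, function(nm) {
    sc <- score_denoised(ds, spec_for(nm, 8L), n_folds, seed, max_latent)
    note("function", nm, 8L, sc)
    sc$rmsecv
  }, 0)
  best_fun <- candidate_functions[pick_min(stage1)]
  fam <- if (best_fun == "haar") "haar"
    else if (startsWith(best_fun, "bior")) "bior"
    else if (startsWith(best_fun, "db")) "db" else "sym"

  # stage 2: order scan within the winning family
  if (fam == "haar") {
    best_name <- "haar"
  } else {
    members <- if (fam == "bior") intersect(order_range, c(1L, 3L, 5L))
      else intersect(order_range, 2:8)
    names_scan <- if (fam == "bior") paste0("bior1.", members)
      else paste0(fam, members)
    if (length(names_scan)) {
      stage2 <- vapply(names_scan, function(nm) {
        sc <- score_denoised(ds, spec_for(nm, 8L), n_folds, seed, max_latent)
        note("order", nm, 8L, sc)
        sc$rmsecv
      }, 0)
      best_name <- names_scan[pick_min(stage2)]
    } else best_name <- best_fun
  }

  # stage 3: level scan for the winning wavelet
  stage3 <- vapply(level_range, function(lev) {
    sc <- score_denoised(ds, spec_for(best_name, as.integer(lev)),
                         n_folds, seed, max_latent)
    note("level", best_name, as.integer(lev), sc)
    sc$rmsecv
  }, 0)
  best_level <- level_range[pick_min(stage3)]

  list(spec = spec_for(best_name, as.integer(best_level)),
       score_table = do.call(rbind, rows))
}
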