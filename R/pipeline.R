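#' Configuration for a full calibration study
#'
#' Describes one end-to-end run: data source, smoothing, the spectral
#' techniques and regression methods to compare, cross-validation schemes,
#' split sizes and the VIP threshold used for effective-wavelength
#' selection.
#'
#' @param sim_config a [simulation_config()] describing the synthetic
#'   dataset, or `NULL` when `data_csv` is given.
#' @param data_csv optional path to a spectra CSV (see
#'   [read_spectra_csv()]); overrides `sim_config`.
#' @param smoothing list with `window`, `polyorder`, `edge_policy` for
#'   [savgol_smooth()].
#' @param transforms subset of `c("raw", "fdr", "cr")`.
#' @param methods subset of `c("MLR", "PCR", "PLS", "SVM")`.
#' @param cv_scheme scheme for PCR/PLS order selection (default
#'   leave-one-out).
#' @param svr_cv_scheme scheme for the SVR grid search (default 5-fold;
#'   leave-one-out over the full grid is disproportionately expensive).
#' @param svr_grid hyperparameter grid for [fit_svr_rbf()].
#' @param max_components,max_lv order caps for PCR/PLS.
#' @param vip_threshold VIP threshold for effective-wavelength selection.
#' @param n_cal,n_val calibration/validation split sizes.
#' @param seed master seed; the split and fold assignments derive from it.
#' @return A list of class `study_config`.
#' @export
study_config <- function(sim_config = simulation_config(),
                         data_csv = NULL,
                         smoothing = list(window = 5L, polyorder = 2L,
                                          edge_policy = "reflect"),
                         transforms = c("raw", "fdr", "cr"),
                         methods = c("MLR", "PCR", "PLS", "SVM"),
                         cv_scheme = cv_loo(),
                         svr_cv_scheme = cv_kfold(5L),
                         svr_grid = svr_default_grid(),
                         max_components = 20L, max_lv = 20L,
                         vip_threshold = 2.0,
                         n_cal = 165L, n_val = 150L,
                         seed = 1L) {
  if (!length(transforms) || !length(methods))
    stop_nspec("config", "need at least one transform and one method")
  transforms <- match.arg(transforms, c("raw", "fdr", "cr"),
                          several.ok = TRUE)
  methods <- match.arg(methods, c("MLR", "PCR", "PLS", "SVM"),
                       several.ok = TRUE)
  structure(list(sim_config = sim_config, data_csv = data_csv,
                 smoothing = smoothing, transforms = transforms,
                 methods = methods, cv_scheme = cv_scheme,
                 svr_cv_scheme = svr_cv_scheme, svr_grid = svr_grid,
                 max_components = max_components, max_lv = max_lv,
                 vip_threshold = vip_threshold,
                 n_cal = check_count(n_cal, "n_cal", 0L),
                 n_val = check_count(n_val, "n_val", 0L),
                 seed = check_count(seed, "seed", 0L)),
            class = "study_config")
}

# rethrow any stage failure with the stage name prepended, so a pipeline
# error always says where it happened
with_stage <- function(stage, expr) {
  withCallingHandlers(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

fit_one_method <- function(method, Xc, yc, config) {
  switch(method,
         MLR = list(model = fit_mlr(Xc, yc), cv_trace = NULL),
         PCR = fit_pcr(Xc, yc, config$max_components, config$cv_scheme,
                       seed = config$seed + 11L),
         PLS = fit_pls(Xc, yc, config$max_lv, config$cv_scheme,
                       seed = config$seed + 12L),
         SVM = fit_svr_rbf(Xc, yc, config$svr_grid, config$svr_cv_scheme,
                           seed = config$seed + 13L))
}

eval_row <- function(method, technique, model, Xc, yc, Xv, yv) {
  ec <- evaluate(yc, predict(model, Xc), split = "calibration")
  ev <- evaluate(yv, predict(model, Xv), split = "validation")
  data.frame(method = method, technique = technique,
             order = if (!is.null(model$selected_order))
               model$selected_order else NA_integer_,
             r2_cal = ec$r2, rmse_cal = ec$rmse, rpd_cal = ec$rpd,
             r2_val = ev$r2, rmse_val = ev$rmse, rpd_val = ev$rpd,
             slope_val = ev$slope, intercept_val = ev$intercept)
}

#' Run the full calibration study
#'
#' Executes the complete workflow: generate (or load) spectra, smooth,
#' split into calibration/validation, transform, fit every requested
#' method on every technique, evaluate both splits, pick the
#' (technique, method) pair with the highest validation RPD (ties: higher
#' validation r2, then smaller order), compute VIP scores from the PLS fit
#' of the best technique, select effective wavelengths at the configured
#' threshold, refit all methods on the selected bands and evaluate again.
#'
#' @param config a [study_config()].
#' @return A `study_report` list: `results` (full-spectrum table),
#'   `effective_results`, `cv_traces`, `correlations`, `vip_profile`,
#'   `effective_wavelengths`, `variable_reduction_pct`, `best`,
#'   `summaries`, and a `provenance` block (seed, sizes, versions).
#' @examples
#' \donttest{
#' cfg <- study_config(sim_config = simulation_config(n_samples = 60, seed = 3),
#'                     transforms = "fdr", methods = "PLS",
#'                     cv_scheme = cv_kfold(5), n_cal = 40, n_val = 20, seed = 3)
#' rep <- run_study(cfg)
#' rep$results
#' }
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  dataset <- with_stage("data", if (!is.null(config$data_csv)) {
    read_spectra_csv(config$data_csv)
  } else {
    simulate_canopy_dataset(config$sim_config)
  })
  smoothed <- with_stage("smooth",
    savgol_smooth(dataset, config$smoothing$window,
                  config$smoothing$polyorder,
                  config$smoothing$edge_policy))
  split <- with_stage("split",
    split_dataset(smoothed, config$n_cal, config$n_val,
                  seed = config$seed + 1L))
  cal <- split$calibration
  val <- split$validation

  results <- list()
  cv_traces <- list()
  correlations <- list()
  pls_models <- list()
  for (tk in config$transforms) {
    tcal <- with_stage(paste0("transform:", tk), apply_transform(cal, tk))
    tval <- with_stage(paste0("transform:", tk), apply_transform(val, tk))
    correlations[[tk]] <- wavelength_correlations(tcal)
    for (method in config$methods) {
      fit <- with_stage(paste(tk, method, sep = ":"),
        fit_one_method(method, tcal$reflectance, tcal$leaf_n, config))
      key <- paste(tk, method, sep = "_")
      if (!is.null(fit$cv_trace)) cv_traces[[key]] <- fit$cv_trace
      if (method == "PLS") pls_models[[tk]] <- fit$model
      results[[key]] <- eval_row(method, tk, fit$model,
                                 tcal$reflectance, tcal$leaf_n,
                                 tval$reflectance, tval$leaf_n)
    }
  }
  results <- do.call(rbind, c(results, make.row.names = FALSE))

  ord <- order(-results$rpd_val, -results$r2_val, results$order,
               na.last = TRUE)
  best <- results[ord[1L], ]

  # VIP always comes from a PLS fit of the best technique, matching the
  # PLS-based selection step of the workflow
  best_tk <- best$technique
  if (is.null(pls_models[[best_tk]])) {
    tcal <- apply_transform(cal, best_tk)
    pls_models[[best_tk]] <- fit_pls(tcal$reflectance, tcal$leaf_n,
                                     config$max_lv, config$cv_scheme,
                                     seed = config$seed + 12L)$model
  }
  vip <- vip_scores(pls_models[[best_tk]], threshold = config$vip_threshold)
  effective <- select_effective_wavelengths(vip, config$vip_threshold)

  effective_results <- NULL
  if (nrow(effective)) {
    tcal <- apply_transform(cal, best_tk)
    tval <- apply_transform(val, best_tk)
    sel_idx <- match(effective$wavelength_nm, tcal$wavelengths)
    Xc <- tcal$reflectance[, sel_idx, drop = FALSE]
    Xv <- tval$reflectance[, sel_idx, drop = FALSE]
    eff <- lapply(config$methods, function(method) {
      fit <- fit_one_method(method, Xc, tcal$leaf_n, config)
      eval_row(method, best_tk, fit$model, Xc, tcal$leaf_n, Xv, tval$leaf_n)
    })
    effective_results <- do.call(rbind, c(eff, make.row.names = FALSE))
  }

  structure(list(
    results = results,
    effective_results = effective_results,
    cv_traces = cv_traces,
    correlations = correlations,
    vip_profile = vip,
    effective_wavelengths = effective,
    variable_reduction_pct = if (nrow(effective))
      report_variable_reduction(length(cal$wavelengths), nrow(effective))
    else NA_real_,
    best = best,
    summaries = list(calibration = dataset_summary(cal$leaf_n),
                     validation = dataset_summary(val$leaf_n),
                     all = dataset_summary(smoothed$leaf_n)),
    provenance = list(seed = config$seed,
                      n_cal = config$n_cal, n_val = config$n_val,
                      transforms = config$transforms,
                      methods = config$methods,
                      vip_threshold = config$vip_threshold,
                      package_version =
                        as.character(utils::packageVersion("nspec")),
                      r_version = paste(R.version$major, R.version$minor,
                                        sep = "."))),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n full-spectrum results:\n")
  print(x$results, digits = 3)
  if (!is.null(x$effective_results)) {
    cat(sprintf(" effective wavelengths (%s): %s  [%.2f%% of bands removed]\n",
                x$best$technique,
                paste(x$effective_wavelengths$wavelength_nm, collapse = ", "),
                x$variable_reduction_pct))
    print(x$effective_results, digits = 3)
  }
  invisible(x)
}

#' Percentage of spectral variables eliminated by wavelength selection
#'
#' @param n_full number of bands in the full spectrum.
#' @param n_selected number of effective wavelengths retained.
#' @return `100 * (n_full - n_selected) / n_full`, rounded to 2 decimals.
#' @examples
#' report_variable_reduction(551, 6) # 98.91
#' @export
report_variable_reduction <- function(n_full, n_selected) {
  n_full <- check_count(n_full, "n_full")
  n_selected <- check_count(n_selected, "n_selected")
  if (n_selected > n_full)
    stop_nspec("config", "n_selected (%d) exceeds n_full (%d)",
               n_selected, n_full)
  round(100 * (n_full - n_selected) / n_full, 2)
}

#' Write a study report to a directory of CSV files plus a JSON manifest
#'
#' Emits `results.csv`, `effective_results.csv`, one
#' `cv_trace_<technique>_<method>.csv` per trace,
#' `correlation_<technique>.csv` per technique, `vip_profile.csv`,
#' `effective_wavelengths.csv`, `config.json` and `manifest.json` (with
#' the provenance block and the MD5 of the config file).
#'
#' @param report a `study_report` from [run_study()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  write.csv(report$results, fp("results.csv"), row.names = FALSE)
  if (!is.null(report$effective_results))
    write.csv(report$effective_results, fp("effective_results.csv"),
              row.names = FALSE)
  for (key in names(report$cv_traces))
    write_cv_trace_csv(report$cv_traces[[key]],
                       fp(sprintf("cv_trace_%s.csv", key)))
  for (tk in names(report$correlations))
    write_correlation_csv(report$correlations[[tk]],
                          fp(sprintf("correlation_%s.csv", tk)))
  write_vip_csv(report$vip_profile, fp("vip_profile.csv"))
  write.csv(report$effective_wavelengths, fp("effective_wavelengths.csv"),
            row.names = FALSE)
  jsonlite::write_json(report$provenance, fp("config.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- c(report$provenance,
                list(config_md5 = unname(tools::md5sum(fp("config.json"))),
                     variable_reduction_pct = report$variable_reduction_pct,
                     files = list.files(dir)))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
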