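# End-to-end orchestration: generate/read -> calibrate -> segment ->
# spectra -> crop -> SNV -> SPXY -> full-spectrum models -> CARS ->
# simplified models -> metrics table -> chemical maps.

#' Pipeline configuration
#'
#' Bundles every knob of [run_pipeline()] with the study defaults. All
#' randomness derives from `design$seed`.
#'
#' @param design A [storage_design()].
#' @param cube_shape Integer `c(lines, samples)` for the synthetic cubes.
#' @param min_nm Effective-range lower bound, nm.
#' @param calib_fraction SPXY calibration fraction.
#' @param max_lv PLSR latent-variable search cap.
#' @param lssvm_log2_range LSSVM hyperparameter search box (log2 units).
#' @param cars_runs CARS Monte-Carlo runs.
#' @param cv_folds Cross-validation folds throughout.
#' @param n_map_eggs How many eggs to map pixel-wise (picked to span the
#'   reference range); their calibrated cubes are retained.
#' @param out_dir Optional output directory; when set, the results bundle
#'   is written there (JSON + CSV + PNG maps).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = storage_design(),
                            cube_shape = c(64L, 64L),
                            min_nm = 435,
                            calib_fraction = 2 / 3,
                            max_lv = 16,
                            lssvm_log2_range = c(-8, 8),
                            cars_runs = 100,
                            cv_folds = 5,
                            n_map_eggs = 3,
                            out_dir = NULL) {
  structure(
    list(design = design, cube_shape = as.integer(cube_shape),
         min_nm = min_nm, calib_fraction = calib_fraction, max_lv = max_lv,
         lssvm_log2_range = lssvm_log2_range, cars_runs = cars_runs,
         cv_folds = cv_folds, n_map_eggs = n_map_eggs, out_dir = out_dir),
    class = "pipeline_config"
  )
}

.model_metrics <- function(model_name, n_wl, fit, cv, x_cal, y_cal,
                           x_pred, y_pred) {
  mc <- compute_metrics(y_cal, predict(fit, x_cal))
  mp <- compute_metrics(y_pred, predict(fit, x_pred))
  tibble::tibble(
    model = model_name, n_wavelengths = n_wl,
    r2_c = mc$r2, rmsec = mc$rmse,
    r2_cv = cv$r2, rmsecv = cv$rmse,
    r2_p = mp$r2, rmsep = mp$rmse
  )
}

#' Run the full S-ovalbumin calibration and mapping pipeline
#'
#' Streams synthetic egg cubes one at a time (cube -> calibration ->
#' ROI -> mean spectrum), so the default 180-egg study never holds more
#' than one cube in memory. Then crops to the effective range, applies
#' SNV, partitions with SPXY, fits full-spectrum PLSR and LSSVM (latent
#' variables and `gamma`/`sigma` selected by five-fold cross-validation),
#' selects feature wavelengths with CARS, refits both learners on the
#' selected subset, assembles the four-row metrics table, and renders
#' pixel-wise chemical maps for a few representative eggs with the
#' simplified LSSVM model.
#'
#' @param config A [pipeline_config()].
#' @return A results bundle (list) with the truth table, split, selected
#'   wavelengths, fitted models, the metrics table (one row per learner x
#'   {full, selected}), chemical maps, and every derived seed. Written to
#'   `config$out_dir` when set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  design <- config$design
  seeds <- list(
    refs = (design$seed + 104729L) %% 2147483647L,
    split_cv = (design$seed + 11L) %% 2147483647L,
    lssvm_grid = (design$seed + 23L) %% 2147483647L,
    cars = (design$seed + 37L) %% 2147483647L,
    lssvm_grid_sel = (design$seed + 53L) %% 2147483647L,
    final_cv = (design$seed + 71L) %% 2147483647L
  )
  grid <- make_wavelength_grid()
  truth <- generate_ground_truth(design)
  refs <- generate_reference_cubes(config$cube_shape, grid$wavelength_nm,
                                   seed = seeds$refs)

  # eggs to keep for mapping: span the reference range
  n <- nrow(truth)
  ord <- order(truth$reference_content)
  map_idx <- unique(ord[round(seq(1, n, length.out = min(config$n_map_eggs, n)))])

  spectra_rows <- matrix(0, n, nrow(grid))
  kept <- list()
  for (i in seq_len(n)) {
    egg <- generate_egg_cube(truth[i, ], config$cube_shape,
                             grid$wavelength_nm,
                             refs$white_profile, refs$dark_level)
    calibrated <- calibrate_cube(egg$cube, refs$white, refs$dark)
    mask <- segment_roi(calibrated)
    spectra_rows[i, ] <- roi_mean_spectrum(calibrated, mask)
    if (i %in% map_idx) {
      kept[[truth$sample_id[i]]] <- list(cube = calibrated, mask = mask)
    }
  }
  spectra_full <- spectra_table(spectra_rows, grid$wavelength_nm,
                                truth$sample_id)
  spectra <- snv_spectra(crop_spectral_range(spectra_full, config$min_nm))

  split <- spxy_split(spectra, truth, config$calib_fraction)
  cal_ids <- split$sample_id[split$subset == "calibration"]
  is_cal <- spectra$sample_id %in% cal_ids
  x_cal <- spectra[is_cal, ]
  x_pred <- spectra[!is_cal, ]
  y_cal <- truth$reference_content[is_cal]
  y_pred <- truth$reference_content[!is_cal]

  fit_pair <- function(x_c, grid_seed) {
    h <- select_n_lv(x_c, y_cal, max_lv = config$max_lv,
                     k = config$cv_folds, seed = seeds$split_cv)
    plsr <- fit_plsr(x_c, y_cal, as.integer(h))
    plsr_cv <- kfold_cv(x_c, y_cal, "plsr", n_lv = as.integer(h),
                        k = config$cv_folds, seed = seeds$final_cv)
    gs <- grid_search_lssvm(x_c, y_cal, config$lssvm_log2_range,
                            k = config$cv_folds, seed = grid_seed)
    lssvm <- fit_lssvm(x_c, y_cal, gs$gamma, gs$sigma)
    lssvm_cv <- kfold_cv(x_c, y_cal, "lssvm", gamma = gs$gamma,
                         sigma = gs$sigma, k = config$cv_folds,
                         seed = seeds$final_cv)
    list(plsr = plsr, plsr_cv = plsr_cv, n_lv = as.integer(h),
         lssvm = lssvm, lssvm_cv = lssvm_cv, grid = gs)
  }

  full <- fit_pair(x_cal, seeds$lssvm_grid)
  cars_res <- cars(x_cal, y_cal, n_runs = config$cars_runs,
                   cv_folds = config$cv_folds, seed = seeds$cars)
  sel <- cars_res$selected_indices
  x_cal_sel <- rebuild_on_features(x_cal, sel)
  x_pred_sel <- rebuild_on_features(x_pred, sel)
  simplified <- fit_pair(x_cal_sel, seeds$lssvm_grid_sel)

  p_full <- ncol(spectra) - 1L
  metrics <- dplyr::bind_rows(
    .model_metrics("lssvm", p_full, full$lssvm, full$lssvm_cv,
                   x_cal, y_cal, x_pred, y_pred),
    .model_metrics("plsr", p_full, full$plsr, full$plsr_cv,
                   x_cal, y_cal, x_pred, y_pred),
    .model_metrics("lssvm", length(sel), simplified$lssvm,
                   simplified$lssvm_cv, x_cal_sel, y_cal, x_pred_sel, y_pred),
    .model_metrics("plsr", length(sel), simplified$plsr,
                   simplified$plsr_cv, x_cal_sel, y_cal, x_pred_sel, y_pred)
  )

  maps <- purrr::imap(kept, function(item, id) {
    predict_pixelwise(item$cube, item$mask, simplified$lssvm,
                      feature_indices = sel, min_nm = config$min_nm)
  })
  map_info <- tibble::tibble(
    sample_id = names(maps),
    reference_content = truth$reference_content[match(names(maps),
                                                      truth$sample_id)],
    map_mean = purrr::map_dbl(maps, function(m) {
      mean(m$values[m$mask], na.rm = TRUE)
    })
  )

  bundle <- list(
    config = config, seeds = seeds, truth = truth, split = split,
    spectra = spectra, cars = cars_res,
    selected_indices = sel,
    selected_wavelengths = cars_res$selected_wavelengths,
    models = list(plsr_full = full$plsr, lssvm_full = full$lssvm,
                  plsr_selected = simplified$plsr,
                  lssvm_selected = simplified$lssvm),
    hyperparameters = list(
      n_lv_full = full$n_lv, n_lv_selected = simplified$n_lv,
      lssvm_full = full$grid[c("log2_gamma", "log2_inv_sigma2")],
      lssvm_selected = simplified$grid[c("log2_gamma", "log2_inv_sigma2")]),
    metrics = metrics, maps = maps, map_info = map_info
  )
  class(bundle) <- "ovaspec_results"
  if (!is.null(config$out_dir)) .write_bundle(bundle, config$out_dir)
  bundle
}

#' @export
print.ovaspec_results <- function(x, ...) {
  cat("<ovaspec_results>\n")
  print(x$metrics)
  cat(sprintf("selected wavelengths (%d): %s nm\n",
              length(x$selected_wavelengths),
              paste(round(x$selected_wavelengths, 1), collapse = ", ")))
  invisible(x)
}

.write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$split, file.path(out_dir, "split.csv"),
                   row.names = FALSE)
  utils::write.csv(
    tibble::tibble(run = seq_along(bundle$cars$rmsecv_trace),
                   retained = bundle$cars$retained_counts,
                   rmsecv = bundle$cars$rmsecv_trace),
    file.path(out_dir, "cars_trace.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(metrics = bundle$metrics,
         selected_indices = bundle$selected_indices,
         selected_wavelengths = bundle$selected_wavelengths,
         hyperparameters = bundle$hyperparameters,
         seeds = bundle$seeds,
         map_info = bundle$map_info),
    file.path(out_dir, "results.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (id in names(bundle$maps)) {
    render_map(bundle$maps[[id]],
               file.path(out_dir, "maps", paste0(id, ".png")))
  }
  invisible(out_dir)
}
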