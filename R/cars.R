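# Competitive adaptive reweighted sampling (CARS) feature-wavelength
# selection: Monte-Carlo subsampling, exponentially decreasing retention
# (EDF), adaptive reweighted sampling (ARS) and subset PLS models.

#' Exponentially decreasing retention ratio (EDF)
#'
#' The fraction of the `p` variables retained at Monte-Carlo run `i` of
#' `n_runs` follows `r_i = a * exp(-k * i)` with
#' `a = (p/2)^(1/(N-1))` and `k = log(p/2)/(N-1)`, so all variables
#' survive the first run (`r_1 = 1`) and exactly two survive the last
#' (`r_N * p = 2`).
#'
#' @param run Run index `i`, `1 <= i <= n_runs` (vectorised).
#' @param n_runs Total number of Monte-Carlo runs `N`.
#' @param p Total number of variables (>= 2).
#' @return Retention ratio(s) in (0, 1\].
#' @export
edf_ratio <- function(run, n_runs, p) {
  if (p < 2) {
    rlang::abort("`p` must be >= 2.", class = "ovaspec_domain_error")
  }
  if (any(run < 1 | run > n_runs)) {
    rlang::abort("`run` must lie in [1, n_runs].",
                 class = "ovaspec_domain_error")
  }
  a <- (p / 2)^(1 / (n_runs - 1))
  k <- log(p / 2) / (n_runs - 1)
  a * exp(-k * run)
}

# LV count for a subset PLS fit: 2% plateau rule on an internal
# cross-validated trace, capped to keep tiny subsets from overfitting.
.cars_pick_lv <- function(x, y, cap, cv_folds) {
  h_max <- max(1, min(cap, ncol(x), nrow(x) - ceiling(nrow(x) / cv_folds) - 1))
  folds <- .make_folds(nrow(x), cv_folds)
  trace <- .pls_cv_rmse_trace(x, y, h_max, folds)
  select_from_trace(trace, 0.02)
}

#' CARS feature-wavelength selection
#'
#' Runs `n_runs` Monte-Carlo iterations on the calibration spectra. Each
#' run, on the currently retained variables: (1) a PLS model is fit to a
#' random `mc_fraction` of the samples and each variable is weighted by
#' the absolute value of its regression coefficient; (2) the EDF schedule
#' ([edf_ratio()]) forces the retained count down by keeping the
#' top-weight variables; (3) adaptive reweighted sampling draws variables
#' with replacement, with probability proportional to the weights, and
#' keeps those drawn at least once; (4) a PLS model on the surviving
#' variables, fit to all calibration samples, records the five-fold
#' RMSECV. The subset from the run with minimum RMSECV wins. Latent
#' variables are chosen per run by internal cross-validation, capped at
#' `min(max_lv, n_retained, n_mc - 1)`.
#'
#' @param x Calibration spectra (matrix or spectra table), typically
#'   SNV-corrected.
#' @param y Calibration reference values.
#' @param n_runs Number of Monte-Carlo sampling runs.
#' @param cv_folds Folds for the recorded RMSECV.
#' @param mc_fraction Fraction of samples drawn (without replacement) per
#'   run.
#' @param seed Integer seed; identical `(x, y, seed)` give identical
#'   results.
#' @param max_lv Cap on latent variables inside subset PLS models.
#' @return An object of class `cars_result`: `selected_indices` (sorted
#'   column indices of the winning subset), `selected_wavelengths` (when
#'   column names carry wavelengths), `rmsecv_trace`, `retained_counts`,
#'   `coefficient_paths` (per-run sparse coefficient records),
#'   `retained_sets`, and `best_run`.
#' @export
cars <- function(x, y, n_runs = 100, cv_folds = 5, mc_fraction = 0.8,
                 seed = NULL, max_lv = 10) {
  xm <- .as_predictor_matrix(x)
  n <- nrow(xm); p <- ncol(xm)
  if (p < 2) {
    rlang::abort("CARS needs at least two variables.",
                 class = "ovaspec_domain_error")
  }
  if (n < cv_folds) {
    rlang::abort("Need at least `cv_folds` samples.",
                 class = "ovaspec_domain_error")
  }
  run_cars <- function() {
    n_mc <- max(cv_folds, round(mc_fraction * n))
    retained <- seq_len(p)
    rmsecv_trace <- numeric(0)
    retained_counts <- integer(0)
    retained_sets <- list()
    coefficient_paths <- list()
    cv_folds_assign <- .make_folds(n, cv_folds)  # fixed: traces comparable
    for (i in seq_len(n_runs)) {
      mc <- sort(sample(n, n_mc))
      x_mc <- xm[mc, retained, drop = FALSE]
      h <- .cars_pick_lv(x_mc, y[mc], max_lv, cv_folds)
      fit <- .pls_fit(x_mc, y[mc], h)
      wgt <- abs(fit$coef_path[, h])
      # EDF: force the count down to the schedule, keeping top weights
      target <- max(2L, as.integer(round(edf_ratio(i, n_runs, p) * p)))
      if (target < length(retained)) {
        keep <- order(-wgt, seq_along(wgt))[seq_len(target)]
        retained <- retained[sort(keep)]
        wgt <- wgt[sort(keep)]
      }
      # ARS: p weighted draws with replacement from the EDF survivors;
      # variables drawn at least once survive. Drawing p times (not the
      # current retained count) keeps late-stage removal gentle, so the
      # trace shows the fast-then-refined two-phase decay and reaches the
      # EDF floor of 2 instead of collapsing geometrically.
      if (sum(wgt) > 0) {
        draws <- sample(length(retained), size = p,
                        replace = TRUE, prob = wgt / sum(wgt))
        survivors <- sort(unique(draws))
        retained <- retained[survivors]
      } else {
        rlang::inform(sprintf(
          "cars: all coefficients zero at run %d; retained set unchanged.", i))
      }
      if (length(retained) < 2) {
        rlang::inform(sprintf(
          "cars: retained set collapsed below 2 at run %d; stopping early.", i))
        break
      }
      h_full <- .cars_pick_lv(xm[, retained, drop = FALSE], y, max_lv, cv_folds)
      fit_full <- .pls_fit(xm[, retained, drop = FALSE], y, h_full)
      rmsecv_trace[i] <- .pls_cv_rmse_trace(
        xm[, retained, drop = FALSE], y, h_full, cv_folds_assign)[h_full]
      retained_counts[i] <- length(retained)
      retained_sets[[i]] <- retained
      coefficient_paths[[i]] <- tibble::tibble(
        index = retained, coef = fit_full$coef_path[, h_full])
    }
    best_run <- which.min(rmsecv_trace)
    selected <- retained_sets[[best_run]]
    wl <- suppressWarnings(as.numeric(colnames(xm)))
    structure(
      list(selected_indices = selected,
           selected_wavelengths = if (all(is.finite(wl))) wl[selected] else NULL,
           rmsecv_trace = rmsecv_trace,
           retained_counts = retained_counts,
           retained_sets = retained_sets,
           coefficient_paths = coefficient_paths,
           best_run = best_run,
           n_runs = length(rmsecv_trace)),
      class = "cars_result"
    )
  }
  if (is.null(seed)) run_cars() else withr::with_seed(seed, run_cars())
}

#' @export
print.cars_result <- function(x, ...) {
  cat(sprintf(
    "<cars_result> %d runs; best run %d (RMSECV %.4g) retains %d variable(s)\n",
    x$n_runs, x$best_run, min(x$rmsecv_trace), length(x$selected_indices)))
  invisible(x)
}

#' Restrict a spectra table to selected feature wavelengths
#'
#' Column subset preserving order and wavelength labels; the indices refer
#' to the band columns (not counting `sample_id`).
#'
#' @param table A spectra table.
#' @param selected_indices Sorted band indices, e.g.
#'   `cars_result$selected_indices`.
#' @return The reduced spectra table.
#' @export
rebuild_on_features <- function(table, selected_indices) {
  if (length(selected_indices) == 0) {
    rlang::abort("Empty feature selection.", class = "ovaspec_domain_error")
  }
  wl <- spectra_wavelengths(table)
  if (any(selected_indices < 1 | selected_indices > length(wl))) {
    rlang::abort("Feature indices out of range.",
                 class = "ovaspec_domain_error")
  }
  dplyr::select(table, "sample_id",
                dplyr::all_of(sprintf("%.4f", wl[selected_indices])))
}
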