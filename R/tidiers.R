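# broom-style tidiers and autoplot methods for fitted objects.

#' Tidy a PLSR model
#'
#' One row per predictor with its regression coefficient (original X
#' scale, centered-y convention).
#'
#' @param x A `plsr_model`.
#' @param ... Unused.
#' @return Tibble with `term`, `wavelength_nm` (when available) and
#'   `estimate`.
#' @method tidy plsr_model
#' @export
tidy.plsr_model <- function(x, ...) {
  tibble::tibble(
    term = seq_along(x$coef),
    wavelength_nm = if (length(x$wavelengths) == length(x$coef))
      x$wavelengths else NA_real_,
    estimate = x$coef
  )
}

#' @rdname tidy.plsr_model
#' @method glance plsr_model
#' @export
glance.plsr_model <- function(x, ...) {
  tibble::tibble(n_lv = x$n_lv, p = length(x$coef),
                 n = if (is.null(x$scores)) NA_integer_ else nrow(x$scores))
}

#' Tidy an LSSVM model
#'
#' One row per training sample with its dual coefficient.
#'
#' @param x An `lssvm_model`.
#' @param ... Unused.
#' @return Tibble with `sample` and `alpha`.
#' @method tidy lssvm_model
#' @export
tidy.lssvm_model <- function(x, ...) {
  tibble::tibble(sample = seq_along(x$alpha), alpha = x$alpha)
}

#' @rdname tidy.lssvm_model
#' @method glance lssvm_model
#' @export
glance.lssvm_model <- function(x, ...) {
  tibble::tibble(n = length(x$alpha), gamma = x$gamma, sigma = x$sigma,
                 kkt_residual = x$kkt_residual)
}

#' Tidy a CARS result
#'
#' One row per Monte-Carlo run with its retained-variable count and
#' recorded cross-validated error.
#'
#' @param x A `cars_result`.
#' @param ... Unused.
#' @return Tibble with `run`, `retained`, `rmsecv`, `is_best`.
#' @method tidy cars_result
#' @export
tidy.cars_result <- function(x, ...) {
  tibble::tibble(
    run = seq_len(x$n_runs),
    retained = x$retained_counts,
    rmsecv = x$rmsecv_trace,
    is_best = seq_len(x$n_runs) == x$best_run
  )
}

#' @rdname tidy.cars_result
#' @method glance cars_result
#' @export
glance.cars_result <- function(x, ...) {
  tibble::tibble(n_runs = x$n_runs, best_run = x$best_run,
                 n_selected = length(x$selected_indices),
                 rmsecv_min = min(x$rmsecv_trace))
}

#' Plot the CARS selection process
#'
#' Two stacked panels over sampling runs: the retained-wavelength count
#' (the exponential-then-refined decay) and the RMSECV of the per-run
#' subset model, with the winning run marked.
#'
#' @param object A `cars_result`.
#' @param ... Unused.
#' @return A ggplot object (facetted).
#' @method autoplot cars_result
#' @export
autoplot.cars_result <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("retained", "rmsecv"),
                        names_to = "panel", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$run, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_run, linetype = 2,
                        colour = "#B2182B") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y",
                        labeller = ggplot2::as_labeller(c(
                          retained = "retained wavelengths",
                          rmsecv = "RMSECV (%)"))) +
    ggplot2::labs(x = "sampling run", y = NULL) +
    ggplot2::theme_minimal()
}
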