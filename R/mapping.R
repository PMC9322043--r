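# Pixel-wise chemical maps: apply a fitted model to every ROI pixel of a
# calibrated cube.

#' Predict S-ovalbumin content for every ROI pixel
#'
#' For each pixel under the mask: crop the pixel spectrum to the effective
#' range (`>= min_nm`), SNV-correct the full cropped spectrum, subset to
#' the model's feature wavelengths, predict, and clip to `clip`. SNV is
#' computed on the full effective range *before* subsetting, matching how
#' the training spectra were produced. Background pixels (and degenerate
#' constant-spectrum pixels, which are counted in a message) carry `NA`.
#'
#' @param cube Calibrated [hypercube()] on the training wavelength grid.
#' @param mask Logical ROI mask (see [segment_roi()]).
#' @param model A `plsr_model` or `lssvm_model` trained on SNV spectra
#'   over the effective band range.
#' @param feature_indices Band indices (into the cropped range) the model
#'   was trained on; `NULL` means the full range.
#' @param min_nm Lower bound of the effective spectral range, nm.
#' @param clip Length-2 prediction clip range, percent.
#' @return An object of class `chemical_map`: `values` (lines x samples
#'   matrix, `NA` off the ROI), `mask`, and `color_range = clip`.
#' @export
predict_pixelwise <- function(cube, mask, model, feature_indices = NULL,
                              min_nm = 435, clip = c(0, 100)) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  if (!identical(dim(mask), d[1:2])) {
    rlang::abort("Mask shape must match the cube.",
                 class = "ovaspec_structure_error")
  }
  keep <- cube$wavelengths_nm >= min_nm
  n_model <- if (inherits(model, "plsr_model")) length(model$x_mean)
             else ncol(model$x)
  idx <- feature_indices %||% seq_len(sum(keep))
  if (length(idx) != n_model) {
    rlang::abort("Wavelength grid mismatch: model expects a different band count.",
                 class = "ovaspec_structure_error")
  }
  values <- matrix(NA_real_, d[1], d[2])
  if (any(mask)) {
    m <- matrix(cube$data, d[1] * d[2], d[3])[as.vector(mask), keep,
                                              drop = FALSE]
    corr <- .snv_rows(m)
    if (any(corr$degenerate)) {
      rlang::inform(sprintf(
        "predict_pixelwise: %d degenerate pixel spectrum(s) set to NA.",
        sum(corr$degenerate)))
    }
    pred <- predict(model, corr$spectra[, idx, drop = FALSE])
    pred <- pmin(pmax(pred, clip[1]), clip[2])
    pred[corr$degenerate] <- NA_real_
    values[mask] <- pred
  }
  structure(list(values = values, mask = mask, color_range = clip),
            class = "chemical_map")
}

#' @export
print.chemical_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf(
    "<chemical_map> %d x %d, %d ROI pixel(s), mean %.1f%% (bar %g-%g%%)\n",
    nrow(x$values), ncol(x$values), sum(x$mask), mean(v, na.rm = TRUE),
    x$color_range[1], x$color_range[2]))
  invisible(x)
}

.map_palette <- function() {
  grDevices::colorRamp(c("#2166AC", "#67A9CF", "#F7F7F7", "#EF8A62",
                         "#B2182B"))
}

#' Render a chemical map to a PNG file
#'
#' Low-content pixels render blue, high-content pixels red, on a linear
#' scale over the map's `color_range`; the background is neutral grey and
#' a vertical colour-bar strip spanning the range is appended on the
#' right. The image is written directly as an RGB array, so rendering is
#' deterministic and device-free.
#'
#' @param map A `chemical_map` from [predict_pixelwise()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
render_map <- function(map, path) {
  stopifnot(inherits(map, "chemical_map"))
  pal <- .map_palette()
  lo <- map$color_range[1]; hi <- map$color_range[2]
  scaled <- pmin(pmax((map$values - lo) / (hi - lo), 0), 1)
  h <- nrow(scaled); w <- ncol(scaled)
  img <- array(0.85, dim = c(h, w, 3))  # neutral background
  ok <- which(!is.na(scaled))
  if (length(ok)) {
    cols <- pal(scaled[ok]) / 255
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[ok] <- cols[, ch]
      img[, , ch] <- plane
    }
  }
  # colour bar: 2-pixel gap + strip, top = hi
  bar_vals <- seq(1, 0, length.out = h)
  bar_cols <- pal(bar_vals) / 255
  bar_w <- max(2L, ceiling(w * 0.06))
  out <- array(1, dim = c(h, w + 2L + bar_w, 3))
  out[, seq_len(w), ] <- img
  for (ch in 1:3) {
    out[, (w + 3):(w + 2 + bar_w), ch] <- matrix(bar_cols[, ch], h, bar_w)
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tryCatch(png::writePNG(out, path),
           error = function(e) {
             rlang::abort(sprintf("Cannot write '%s': %s",
                                  path, conditionMessage(e)),
                          class = "ovaspec_io_error")
           })
  invisible(path)
}

#' Plot a chemical map with ggplot2
#'
#' Interactive counterpart of [render_map()]: same linear blue-to-red
#' scale over the map's colour range, background in neutral grey.
#'
#' @param object A `chemical_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot chemical_map
#' @export
autoplot.chemical_map <- function(object, ...) {
  df <- tidyr::expand_grid(line = seq_len(nrow(object$values)),
                           sample = seq_len(ncol(object$values)))
  df$content <- as.vector(t(object$values))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$line,
                                   fill = .data$content)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(
      colours = c("#2166AC", "#67A9CF", "#F7F7F7", "#EF8A62", "#B2182B"),
      limits = object$color_range, na.value = "grey85",
      name = "S-ovalbumin (%)") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}
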