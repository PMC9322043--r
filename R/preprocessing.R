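# SNV scatter correction and SPXY calibration/prediction partitioning.

#' Standard normal variate correction of one spectrum
#'
#' Centers the spectrum on its own mean and scales by its own sample
#' standard deviation (n - 1 denominator), removing per-sample
#' multiplicative scatter and additive baseline offsets:
#' \deqn{x_{cor} = (x - \bar{x}) / \sqrt{\sum (x - \bar{x})^2 / (N - 1)}}
#'
#' @param x Numeric spectrum, length >= 2, non-constant.
#' @return Corrected spectrum with mean 0 and sample SD 1.
#' @examples
#' snv(c(1, 2, 3))  # -1 0 1
#' @export
snv <- function(x) {
  if (length(x) < 2) {
    rlang::abort("SNV needs at least two bands.",
                 class = "ovaspec_degenerate_spectrum")
  }
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    rlang::abort("Constant spectrum: SNV standard deviation is zero.",
                 class = "ovaspec_degenerate_spectrum")
  }
  (x - mean(x)) / s
}

#' SNV-correct every spectrum in a table
#'
#' Applies [snv()] row-wise (one spectrum per sample).
#'
#' @param table A spectra table from [spectra_table()].
#' @return The table with each row SNV-corrected.
#' @export
snv_spectra <- function(table) {
  m <- spectra_matrix(table)
  corrected <- t(apply(m, 1, snv))
  spectra_table(corrected, spectra_wavelengths(table), table$sample_id)
}

# Row-wise SNV on a plain matrix, flagging constant rows instead of
# erroring (used for pixel-wise prediction where dead pixels may occur).
.snv_rows <- function(m) {
  mu <- rowMeans(m)
  centered <- m - mu
  s <- sqrt(rowSums(centered^2) / (ncol(m) - 1))
  bad <- !is.finite(s) | s == 0
  s[bad] <- 1
  list(spectra = centered / s, degenerate = bad)
}

#' SPXY partitioning into calibration and prediction sets
#'
#' Sample set partitioning based on joint X-Y distances. Pairwise distances
#' in predictor space (Euclidean) and response space (absolute difference)
#' are each normalised by their maximum over all pairs and summed; the
#' calibration set is seeded with the maximally distant pair, then grown
#' greedily by the sample whose minimum joint distance to the already
#' chosen set is largest, until `round(calib_fraction * n)` samples are
#' selected. The remainder forms the prediction set. Deterministic; ties
#' are broken by the lowest sample index.
#'
#' @param x_table Spectra table (typically SNV-corrected, cropped).
#' @param reference Tibble with `sample_id` and `reference_content`
#'   aligned to `x_table` (joined by `sample_id`).
#' @param calib_fraction Fraction of samples assigned to calibration.
#' @return Tibble with columns `sample_id` and `subset`
#'   (`"calibration"` / `"prediction"`).
#' @export
spxy_split <- function(x_table, reference, calib_fraction = 2 / 3) {
  n <- nrow(x_table)
  if (n < 3) {
    rlang::abort("SPXY needs at least three samples.",
                 class = "ovaspec_domain_error")
  }
  ref <- dplyr::left_join(dplyr::select(x_table, "sample_id"),
                          reference, by = "sample_id")
  if (any(is.na(ref$reference_content))) {
    rlang::abort("Every sample needs a reference value.",
                 class = "ovaspec_structure_error")
  }
  x <- spectra_matrix(x_table)
  y <- ref$reference_content
  dx <- as.matrix(stats::dist(x))
  dy <- abs(outer(y, y, "-"))
  mx <- max(dx); my <- max(dy)
  if (mx == 0 && my == 0) {
    rlang::warn("All samples identical in X and y; splitting by index.")
    d <- matrix(0, n, n)
  } else {
    if (mx == 0) rlang::warn("All X distances zero; using y distances only.")
    if (my == 0) rlang::warn("All y distances zero; using X distances only.")
    d <- (if (mx > 0) dx / mx else 0) + (if (my > 0) dy / my else 0)
  }
  n_cal <- round(calib_fraction * n)
  # seed with the maximally distant pair (lowest indices on ties)
  flat <- which(d == max(d), arr.ind = TRUE)
  flat <- flat[flat[, 1] < flat[, 2], , drop = FALSE]
  if (nrow(flat) == 0) flat <- matrix(c(1L, 2L), 1)  # fully degenerate data
  pick <- flat[order(flat[, 1], flat[, 2])[1], ]
  selected <- as.integer(pick)
  remaining <- setdiff(seq_len(n), selected)
  while (length(selected) < n_cal) {
    min_d <- apply(d[remaining, selected, drop = FALSE], 1, min)
    best <- remaining[which.max(min_d)]  # which.max: first (lowest) index wins
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  tibble::tibble(
    sample_id = x_table$sample_id,
    subset = ifelse(seq_len(n) %in% selected, "calibration", "prediction")
  )
}
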