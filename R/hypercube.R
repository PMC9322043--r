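# Hypercube container and ENVI-dialect I/O.

#' Hyperspectral data cube
#'
#' Light container for a lines x samples x bands array with a strictly
#' ascending wavelength axis. Holds raw counts before calibration and
#' dimensionless transmittance after [calibrate_cube()].
#'
#' @param data 3-D numeric array, dimensions `c(lines, samples, bands)`.
#' @param wavelengths_nm Strictly ascending numeric vector, length equal to
#'   the third dimension of `data`.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths_nm) {
  if (!is.array(data) || length(dim(data)) != 3) {
    rlang::abort("`data` must be a 3-D array (lines x samples x bands).",
                 class = "ovaspec_structure_error")
  }
  if (dim(data)[3] != length(wavelengths_nm)) {
    rlang::abort("Band dimension must match the wavelength vector length.",
                 class = "ovaspec_structure_error")
  }
  if (is.unsorted(wavelengths_nm, strictly = TRUE)) {
    rlang::abort("`wavelengths_nm` must be strictly ascending.",
                 class = "ovaspec_structure_error")
  }
  structure(list(data = data, wavelengths_nm = as.numeric(wavelengths_nm)),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<hypercube> %d lines x %d samples x %d bands (%.1f-%.1f nm)\n",
    d[1], d[2], d[3], min(x$wavelengths_nm), max(x$wavelengths_nm)))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Write a cube as ENVI raw + header
#'
#' Writes band-interleaved-by-line (BIL) little-endian 32-bit floats to
#' `<path>.raw` and an ASCII header with a `wavelength = {...}` block to
#' `<path>.hdr`.
#'
#' @param cube A [hypercube()].
#' @param path Output path without extension.
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    "description = {ovaspec hyperspectral cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bil",
    "byte order = 0",
    "wavelength units = Nanometers",
    "wavelength = {",
    paste0(" ", paste(sprintf("%.17g", cube$wavelengths_nm), collapse = ",\n ")),
    "}"
  )
  writeLines(hdr, paste0(path, ".hdr"))
  # BIL: line slowest, then band, then sample fastest
  con <- file(paste0(path, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.vector(aperm(cube$data, c(2, 3, 1))), con,
           size = 4L, endian = "little")
  invisible(path)
}

.parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  get_scalar <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?mi)^\\s*", key,
                                        "\\s*=\\s*([^\\n{]+)"), txt, perl = TRUE))[[1]]
    if (length(m) < 2) NULL else trimws(m[2])
  }
  get_block <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?si)", key,
                                        "\\s*=\\s*\\{(.*?)\\}"), txt, perl = TRUE))[[1]]
    if (length(m) < 2) NULL else m[2]
  }
  wl_block <- get_block("wavelength")
  list(
    samples = as.integer(get_scalar("samples")),
    lines = as.integer(get_scalar("lines")),
    bands = as.integer(get_scalar("bands")),
    data_type = as.integer(get_scalar("data type")),
    interleave = tolower(get_scalar("interleave") %||% "bil"),
    byte_order = as.integer(get_scalar("byte order") %||% "0"),
    offset = as.integer(get_scalar("header offset") %||% "0"),
    wavelengths = if (is.null(wl_block)) NULL else
      as.numeric(strsplit(gsub("\\s", "", wl_block), ",")[[1]])
  )
}

#' Read an ENVI-dialect cube
#'
#' Accepts `bil`, `bsq` or `bip` interleave and 32-bit float (data type 4)
#' or 64-bit float (data type 5) payloads; wavelengths are parsed from the
#' header's `wavelength` block.
#'
#' @param path Path without extension, or path to the `.hdr`/`.raw` file.
#' @return A [hypercube()].
#' @export
read_envi <- function(path) {
  base <- sub("\\.(hdr|raw)$", "", path)
  hdr_path <- paste0(base, ".hdr")
  raw_path <- paste0(base, ".raw")
  if (!file.exists(hdr_path) || !file.exists(raw_path)) {
    rlang::abort(sprintf("ENVI pair '%s.{hdr,raw}' not found.", base),
                 class = "ovaspec_io_error")
  }
  h <- .parse_envi_header(hdr_path)
  if (is.null(h$wavelengths)) {
    rlang::abort("Header has no `wavelength` block.",
                 class = "ovaspec_io_error")
  }
  size <- switch(as.character(h$data_type), "4" = 4L, "5" = 8L,
                 rlang::abort("Only ENVI data types 4 and 5 are supported.",
                              class = "ovaspec_io_error"))
  endian <- if (h$byte_order == 0) "little" else "big"
  n <- h$samples * h$lines * h$bands
  con <- file(raw_path, "rb")
  on.exit(close(con))
  if (h$offset > 0) readBin(con, "raw", n = h$offset)
  vec <- readBin(con, "numeric", n = n, size = size, endian = endian)
  data <- switch(h$interleave,
    bil = aperm(array(vec, dim = c(h$samples, h$bands, h$lines)), c(3, 1, 2)),
    bsq = aperm(array(vec, dim = c(h$samples, h$lines, h$bands)), c(2, 1, 3)),
    bip = aperm(array(vec, dim = c(h$bands, h$samples, h$lines)), c(3, 2, 1)),
    rlang::abort("Unsupported interleave (expected bil, bsq or bip).",
                 class = "ovaspec_io_error")
  )
  hypercube(data, h$wavelengths)
}

#' Calibrate a raw cube against white and dark references
#'
#' Converts raw counts to transmittance by the standard reflectance/
#' transmittance correction `(I_o - I_d) / (I_w - I_d)`, removing dark
#' current and illumination non-uniformity. Voxels whose white-minus-dark
#' denominator is smaller than `eps` in magnitude are set to 0 and counted
#' in a message, keeping the output finite.
#'
#' @param raw,white,dark [hypercube()]s sharing shape and wavelength grid.
#' @param eps Degenerate-denominator guard (> 0).
#' @return Calibrated transmittance [hypercube()].
#' @export
calibrate_cube <- function(raw, white, dark, eps = 1e-6) {
  for (cb in list(raw, white, dark)) stopifnot(inherits(cb, "hypercube"))
  if (!identical(dim(raw$data), dim(white$data)) ||
      !identical(dim(raw$data), dim(dark$data))) {
    rlang::abort("Raw, white and dark cubes must share the same shape.",
                 class = "ovaspec_structure_error")
  }
  if (max(abs(raw$wavelengths_nm - white$wavelengths_nm),
          abs(raw$wavelengths_nm - dark$wavelengths_nm)) > 1e-9) {
    rlang::abort("Raw, white and dark cubes must share the wavelength grid.",
                 class = "ovaspec_structure_error")
  }
  denom <- white$data - dark$data
  bad <- abs(denom) < eps
  out <- (raw$data - dark$data) / denom
  if (any(bad)) {
    out[bad] <- 0
    rlang::inform(sprintf(
      "calibrate_cube: %d voxel(s) had |white - dark| < eps; set to 0.",
      sum(bad)))
  }
  hypercube(out, raw$wavelengths_nm)
}

#' Segment the egg region of interest
#'
#' Thresholds the single band nearest `band_nm` (no interpolation): pixels
#' with calibrated transmittance strictly above `threshold` form the ROI.
#' The defaults reflect a high-transmission band at 700.4 nm and a 0.1
#' transmittance cut separating egg from background.
#'
#' @param cube Calibrated [hypercube()].
#' @param band_nm Wavelength of the thresholding band, nm.
#' @param threshold Transmittance threshold (strict `>`).
#' @return Logical lines x samples matrix; attribute `band_nm` records the
#'   band actually used.
#' @export
segment_roi <- function(cube, band_nm = 700.4, threshold = 0.1) {
  stopifnot(inherits(cube, "hypercube"))
  idx <- which.min(abs(cube$wavelengths_nm - band_nm))
  mask <- cube$data[, , idx] > threshold
  if (!any(mask)) {
    rlang::abort("No pixel exceeds the ROI threshold (ROI not found).",
                 class = "ovaspec_roi_error")
  }
  attr(mask, "band_nm") <- cube$wavelengths_nm[idx]
  mask
}

#' Mean spectrum over a pixel mask
#'
#' Per-band arithmetic mean over the masked pixels only; background pixels
#' contribute nothing.
#'
#' @param cube A [hypercube()].
#' @param mask Logical lines x samples matrix with at least one `TRUE`.
#' @return Numeric spectrum, one value per band.
#' @export
roi_mean_spectrum <- function(cube, mask) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  if (!identical(dim(mask), d[1:2])) {
    rlang::abort("Mask shape must match the cube's spatial shape.",
                 class = "ovaspec_structure_error")
  }
  if (!any(mask)) {
    rlang::abort("Mask is empty.", class = "ovaspec_roi_error")
  }
  m <- matrix(cube$data, d[1] * d[2], d[3])
  colMeans(m[as.vector(mask), , drop = FALSE])
}

#' Assemble a spectra table
#'
#' Tibble-first container for n samples x p bands spectra: `sample_id`
#' column plus one numeric column per band, named by its wavelength
#' (four decimals), so the table survives dplyr verbs and round-trips to
#' CSV with a wavelength header row.
#'
#' @param spectra n x p numeric matrix.
#' @param wavelengths_nm Ascending length-p wavelength vector.
#' @param sample_ids Length-n character vector.
#' @return A tibble.
#' @export
spectra_table <- function(spectra, wavelengths_nm, sample_ids) {
  spectra <- as.matrix(spectra)
  stopifnot(ncol(spectra) == length(wavelengths_nm),
            nrow(spectra) == length(sample_ids))
  if (any(!is.finite(spectra))) {
    rlang::abort("Spectra must be finite.", class = "ovaspec_structure_error")
  }
  colnames(spectra) <- sprintf("%.4f", wavelengths_nm)
  dplyr::bind_cols(tibble::tibble(sample_id = sample_ids),
                   tibble::as_tibble(spectra))
}

#' Numeric spectra matrix of a spectra table
#' @param table A spectra table from [spectra_table()].
#' @return n x p numeric matrix with wavelength column names.
#' @export
spectra_matrix <- function(table) {
  as.matrix(table[, setdiff(names(table), "sample_id"), drop = FALSE])
}

#' Wavelengths of a spectra table
#' @param table A spectra table from [spectra_table()].
#' @return Numeric wavelength vector parsed from the column names.
#' @export
spectra_wavelengths <- function(table) {
  as.numeric(setdiff(names(table), "sample_id"))
}

#' Extract mean ROI spectra from a set of cubes
#'
#' Calibrates each raw cube (when references are supplied), segments the
#' ROI, and stacks the per-cube mean ROI spectra into a spectra table.
#'
#' @param cubes List of [hypercube()]s.
#' @param sample_ids Character vector, one id per cube.
#' @param white,dark Optional shared reference cubes; if supplied each cube
#'   is calibrated first.
#' @param band_nm,threshold Segmentation parameters, see [segment_roi()].
#' @return A spectra table (full band range; crop afterwards with
#'   [crop_spectral_range()]).
#' @export
extract_spectra <- function(cubes, sample_ids, white = NULL, dark = NULL,
                            band_nm = 700.4, threshold = 0.1) {
  stopifnot(length(cubes) == length(sample_ids))
  specs <- purrr::map(cubes, function(cb) {
    if (!is.null(white)) cb <- calibrate_cube(cb, white, dark)
    roi_mean_spectrum(cb, segment_roi(cb, band_nm, threshold))
  })
  spectra_table(do.call(rbind, specs), cubes[[1]]$wavelengths_nm, sample_ids)
}

#' Crop a spectra table to the effective spectral range
#'
#' Retains bands at or above `min_nm`. On the nominal 478-band grid the
#' default cut at 435 nm leaves exactly 449 effective bands; the region
#' below is dominated by sensor noise.
#'
#' @param table A spectra table.
#' @param min_nm Minimum retained wavelength, nm.
#' @return The cropped spectra table.
#' @export
crop_spectral_range <- function(table, min_nm = 435) {
  wl <- spectra_wavelengths(table)
  keep <- wl >= min_nm
  if (!any(keep)) {
    rlang::abort("No band at or above `min_nm`; nothing retained.",
                 class = "ovaspec_structure_error")
  }
  dplyr::select(table, "sample_id",
                dplyr::all_of(sprintf("%.4f", wl[keep])))
}
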