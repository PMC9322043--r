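test_that("calibration implements the white/dark correction", {
  ones <- matrix(1, 8, 8)
  raw <- toy_cube(55 * ones)
  white <- toy_cube(100 * ones)
  dark <- toy_cube(10 * ones)
  cal <- calibrate_cube(raw, white, dark)
  expect_equal(unique(as.vector(cal$data)), 0.5)  # (55-10)/(100-10)
  expect_equal(calibrate_cube(dark, white, dark)$data, array(0, dim = c(8, 8, 4)))
  expect_equal(calibrate_cube(white, white, dark)$data, array(1, dim = c(8, 8, 4)))
})

test_that("degenerate calibration denominators yield finite zeros", {
  ones <- matrix(1, 8, 8)
  raw <- toy_cube(50 * ones)
  white <- toy_cube(10 * ones)
  dark <- toy_cube(10 * ones)   # white == dark everywhere
  expect_message(cal <- calibrate_cube(raw, white, dark), "eps")
  expect_true(all(is.finite(cal$data)))
  expect_true(all(cal$data == 0))
})

test_that("calibration rejects mismatched cubes", {
  a <- toy_cube(matrix(1, 8, 8))
  b <- toy_cube(matrix(1, 9, 8))
  expect_error(calibrate_cube(a, b, a), class = "ovaspec_structure_error")
  c2 <- toy_cube(matrix(1, 8, 8), wavelengths = c(500, 600, 700, 801))
  expect_error(calibrate_cube(a, a, c2), class = "ovaspec_structure_error")
})

test_that("calibration stays in [0, 1] when dark <= raw <= white", {
  set.seed(1)
  d <- array(runif(8 * 8 * 4, 0, 10), dim = c(8, 8, 4))
  w <- d + array(runif(8 * 8 * 4, 50, 100), dim = c(8, 8, 4))
  o <- d + (w - d) * array(runif(8 * 8 * 4), dim = c(8, 8, 4))
  wl <- c(500, 600, 700, 800)
  cal <- calibrate_cube(hypercube(o, wl), hypercube(w, wl), hypercube(d, wl))
  expect_true(all(cal$data >= 0 & cal$data <= 1))
})

test_that("ROI segmentation thresholds the band nearest 700.4 nm", {
  ds <- fixture_dataset
  cal <- calibrate_cube(ds$cubes[[2]], ds$white, ds$dark)
  mask <- segment_roi(cal)
  expect_gte(mean(mask == ds$masks[[2]]), 0.99)
  expect_lt(abs(attr(mask, "band_nm") - 700.4), 1.27)  # one grid step
  # mask idempotence: masking the cube then re-segmenting gives same mask
  masked <- cal
  bg <- !mask
  for (b in seq_along(cal$wavelengths_nm)) {
    plane <- masked$data[, , b]
    plane[bg] <- 0
    masked$data[, , b] <- plane
  }
  mask2 <- segment_roi(masked)
  expect_identical(as.vector(mask2), as.vector(mask))
  # threshold below every value selects everything
  expect_true(all(segment_roi(cal, threshold = -1)))
  # all-background cube has no ROI
  expect_error(segment_roi(toy_cube(matrix(0.01, 8, 8))),
               class = "ovaspec_roi_error")
})

test_that("ROI mean spectrum averages masked pixels only", {
  values <- matrix(0.01, 6, 6)
  values[2, 2] <- 0.6
  values[3, 3] <- 0.8
  cube <- toy_cube(values)
  one <- matrix(FALSE, 6, 6); one[2, 2] <- TRUE
  expect_equal(roi_mean_spectrum(cube, one), rep(0.6, 4))
  two <- one; two[3, 3] <- TRUE
  expect_equal(roi_mean_spectrum(cube, two), rep(0.7, 4))  # (a + b) / 2
  expect_equal(roi_mean_spectrum(toy_cube(matrix(0.3, 6, 6)),
                                 matrix(TRUE, 6, 6)), rep(0.3, 4))
  expect_error(roi_mean_spectrum(cube, matrix(FALSE, 6, 6)),
               class = "ovaspec_roi_error")
  expect_error(roi_mean_spectrum(cube, matrix(TRUE, 5, 6)),
               class = "ovaspec_structure_error")
})

test_that("spectral cropping keeps exactly the effective bands", {
  sp <- fixture_spectra_full
  expect_equal(ncol(sp) - 1L, 478L)
  cropped <- crop_spectral_range(sp)
  expect_equal(ncol(cropped) - 1L, 449L)
  expect_true(all(spectra_wavelengths(cropped) >= 435))
  # below the first wavelength: identity
  expect_identical(crop_spectral_range(sp, min_nm = 0), sp)
  expect_error(crop_spectral_range(sp, min_nm = 2000),
               class = "ovaspec_structure_error")
})

test_that("ENVI write/read round-trips cubes", {
  ds <- fixture_dataset
  cube <- ds$cubes[[1]]
  base <- file.path(withr::local_tempdir(), "egg")
  write_envi(cube, base)
  back <- read_envi(base)
  expect_equal(back$wavelengths_nm, cube$wavelengths_nm)  # %.17g exact
  expect_equal(back$data, cube$data, tolerance = 1e-6)    # float32 storage
  # second trip is bit-stable
  write_envi(back, paste0(base, "2"))
  back2 <- read_envi(paste0(base, "2"))
  expect_identical(back2$data, back$data)
  expect_identical(back2$wavelengths_nm, back$wavelengths_nm)
})

test_that("ENVI reader accepts bsq and bip interleaves", {
  cube <- toy_cube(matrix(seq_len(30) / 10, 5, 6),
                   wavelengths = c(500, 600, 700))
  cube$data[2, 3, 2] <- 9.5   # break symmetry
  base <- file.path(withr::local_tempdir(), "cube")
  write_envi(cube, base)
  # rewrite the payload in bsq and bip order with matching headers
  for (il in c("bsq", "bip")) {
    perm <- switch(il, bsq = c(2, 1, 3), bip = c(3, 2, 1))
    con <- file(paste0(base, "_", il, ".raw"), "wb")
    writeBin(as.vector(aperm(cube$data, perm)), con, size = 4,
             endian = "little")
    close(con)
    hdr <- readLines(paste0(base, ".hdr"))
    writeLines(sub("interleave = bil", paste("interleave =", il), hdr),
               paste0(base, "_", il, ".hdr"))
    back <- read_envi(paste0(base, "_", il))
    expect_equal(back$data, cube$data, tolerance = 1e-6)
  }
})

test_that("hypercube constructor validates structure", {
  expect_error(hypercube(matrix(1, 2, 2), 1:2),
               class = "ovaspec_structure_error")
  expect_error(hypercube(array(1, c(2, 2, 3)), c(1, 2)),
               class = "ovaspec_structure_error")
  expect_error(hypercube(array(1, c(2, 2, 3)), c(3, 2, 1)),
               class = "ovaspec_structure_error")
})
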