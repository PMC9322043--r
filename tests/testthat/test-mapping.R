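# A single trained-model context shared across mapping tests.
local({
  ds <- fixture_dataset
  truth <- ds$truth
  x <- spectra_matrix(fixture_spectra)
  y <- truth$reference_content
  assign("map_model", fit_plsr(x, y, 4L), envir = topenv())
  cal <- calibrate_cube(ds$cubes[[5]], ds$white, ds$dark)
  assign("map_cube", cal, envir = topenv())
  assign("map_mask", segment_roi(cal), envir = topenv())
})

test_that("pixel-wise prediction covers the ROI and nothing else", {
  map <- predict_pixelwise(map_cube, map_mask, map_model)
  expect_s3_class(map, "chemical_map")
  expect_true(all(is.finite(map$values[map$mask])))
  expect_true(all(is.na(map$values[!map$mask])))
  expect_true(all(map$values[map$mask] >= 0 & map$values[map$mask] <= 100))
  # per-egg map mean tracks the reference chemistry
  ref <- fixture_dataset$truth$reference_content[5]
  expect_lt(abs(mean(map$values[map$mask]) - ref), 8)
})

test_that("mapping is deterministic and consistent with the mean spectrum", {
  m1 <- predict_pixelwise(map_cube, map_mask, map_model)
  m2 <- predict_pixelwise(map_cube, map_mask, map_model)
  expect_identical(m1$values, m2$values)
  # linear model: mean of pixel predictions ~ prediction on the mean
  # ROI spectrum (SNV nonlinearity tolerance)
  mean_spec <- roi_mean_spectrum(map_cube, map_mask)
  keep <- map_cube$wavelengths_nm >= 435
  pred_mean <- predict(map_model, matrix(snv(mean_spec[keep]), 1))
  expect_lt(abs(mean(m1$values[m1$mask]) - pred_mean), 2)
})

test_that("identical pixel spectra give identical map values", {
  values <- matrix(0.01, 10, 10)
  values[3, 3] <- values[7, 7] <- 0.5
  wl <- make_wavelength_grid()$wavelength_nm
  data <- array(rep(as.vector(values), length(wl)), c(10, 10, length(wl)))
  # give bands a shape so SNV is defined
  data <- sweep(data, 3, seq(0.8, 1.2, length.out = length(wl)), "*")
  cube <- hypercube(data, wl)
  mask <- values > 0.1
  map <- predict_pixelwise(cube, mask, map_model)
  expect_equal(map$values[3, 3], map$values[7, 7])
})

test_that("all-background masks and grid mismatches are handled", {
  mask0 <- matrix(FALSE, nrow(map_mask), ncol(map_mask))
  map <- predict_pixelwise(map_cube, mask0, map_model)
  expect_true(all(is.na(map$values)))
  expect_error(
    predict_pixelwise(map_cube, map_mask, map_model,
                      feature_indices = 1:10),
    class = "ovaspec_structure_error")
  expect_error(predict_pixelwise(map_cube, matrix(TRUE, 3, 3), map_model),
               class = "ovaspec_structure_error")
})

test_that("degenerate pixel spectra become sentinels, with a message", {
  cube <- map_cube
  plane_idx <- which(map_mask, arr.ind = TRUE)[1, ]
  cube$data[plane_idx[1], plane_idx[2], ] <- 0.42  # constant spectrum
  expect_message(
    map <- predict_pixelwise(cube, map_mask, map_model),
    "degenerate")
  expect_true(is.na(map$values[plane_idx[1], plane_idx[2]]))
})

test_that("rendered maps land on disk with a colour bar strip", {
  dir <- withr::local_tempdir()
  map <- predict_pixelwise(map_cube, map_mask, map_model)
  path <- file.path(dir, "egg.png")
  render_map(map, path)
  expect_true(file.exists(path))
  img <- png::readPNG(path)
  expect_gt(dim(img)[2], ncol(map$values))  # colour bar appended
  expect_s3_class(autoplot(map), "ggplot")
})

test_that("extreme maps saturate the linear colour scale", {
  mask <- matrix(TRUE, 4, 4)
  hi <- structure(list(values = matrix(100, 4, 4), mask = mask,
                       color_range = c(0, 100)), class = "chemical_map")
  lo <- structure(list(values = matrix(0, 4, 4), mask = mask,
                       color_range = c(0, 100)), class = "chemical_map")
  pal <- grDevices::colorRamp(c("#2166AC", "#67A9CF", "#F7F7F7",
                                "#EF8A62", "#B2182B"))
  dir <- withr::local_tempdir()
  render_map(hi, file.path(dir, "hi.png"))
  render_map(lo, file.path(dir, "lo.png"))
  img_hi <- png::readPNG(file.path(dir, "hi.png"))
  img_lo <- png::readPNG(file.path(dir, "lo.png"))
  # ROI corner pixel: red channel dominates at the top of the scale,
  # blue at the bottom
  expect_gt(img_hi[1, 1, 1], img_hi[1, 1, 3])
  expect_gt(img_lo[1, 1, 3], img_lo[1, 1, 1])
})

test_that("a high-content egg renders almost entirely in the top quartile", {
  ds <- fixture_dataset
  i <- which.max(ds$truth$reference_content)
  cal <- calibrate_cube(ds$cubes[[i]], ds$white, ds$dark)
  mask <- segment_roi(cal)
  map <- predict_pixelwise(cal, mask, map_model)
  if (ds$truth$reference_content[i] >= 85) {
    frac_top <- mean(map$values[mask] >= 75)
    expect_gte(frac_top, 0.9)
  } else {
    skip("fixture has no high-content egg")
  }
})
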