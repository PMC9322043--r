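# Shared desk-scale fixtures, built once per test run.

small_design <- function(seed = 42L) {
  storage_design(storage_days = c(0L, 9L, 18L, 27L), eggs_per_day = 4L,
                 seed = seed)
}

# 16 eggs, 24x24 cubes: enough structure for every pipeline stage.
local({
  ds <- generate_dataset(small_design(), cube_shape = c(24L, 24L))
  assign("fixture_dataset", ds, envir = topenv())
  sp <- extract_spectra(ds$cubes, ds$truth$sample_id, ds$white, ds$dark)
  assign("fixture_spectra_full", sp, envir = topenv())
  assign("fixture_spectra",
         snv_spectra(crop_spectral_range(sp)), envir = topenv())
})

# Deterministic toy cube: constant-per-pixel values, handy for exact checks.
toy_cube <- function(values, wavelengths = c(500, 600, 700, 800)) {
  lines <- nrow(values); samples <- ncol(values)
  data <- array(rep(as.vector(values), length(wavelengths)),
                dim = c(lines, samples, length(wavelengths)))
  hypercube(data, wavelengths)
}
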