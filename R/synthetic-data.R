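# Synthetic study generator: seeded egg transmittance cubes, white/dark
# references, and spectrophotometric ground truth with the statistical
# structure the downstream chemometrics assumes.

#' Construct the nominal instrument wavelength grid
#'
#' The emulated line-scan instrument records 478 bands across 401--1002 nm.
#' Bands below 435 nm carry too little signal to be useful and are dropped
#' downstream; the grid is built piecewise (29 bands on 401--434.5 nm, 449
#' bands on 435--1002 nm) so the effective-band count after cropping is
#' exactly 449.
#'
#' @return A tibble with columns `band` (1..478), `wavelength_nm`
#'   (strictly ascending) and `effective` (`TRUE` for the 449 bands at or
#'   above 435 nm).
#' @examples
#' grid <- make_wavelength_grid()
#' sum(grid$effective)  # 449
#' @export
make_wavelength_grid <- function() {
  low <- seq(401, 434.5, length.out = 29L)
  high <- seq(435, 1002, length.out = 449L)
  tibble::tibble(
    band = seq_len(478L),
    wavelength_nm = c(low, high),
    effective = rep(c(FALSE, TRUE), c(29L, 449L))
  )
}

#' Expected S-ovalbumin fraction as a function of storage time
#'
#' Ovalbumin converts irreversibly to its thermostable S-form during
#' storage; group means rise monotonically with storage day. The expected
#' fraction is modelled as a four-parameter logistic
#' \deqn{f(d) = L + (U - L) / (1 + e^{-k (d - m)})}
#' whose defaults span roughly 11--94% over a four-week storage window at
#' room temperature.
#'
#' @param day Storage time in days (vectorised, non-negative).
#' @param lower,upper Lower/upper asymptotes as fractions.
#' @param rate Logistic growth rate per day.
#' @param midpoint Day of fastest conversion.
#' @return Expected S-ovalbumin fraction in (lower, upper).
#' @export
storage_curve <- function(day, lower = 0.11, upper = 0.95, rate = 0.25,
                          midpoint = 12) {
  if (any(day < 0)) {
    rlang::abort("`day` must be non-negative.", class = "ovaspec_domain_error")
  }
  lower + (upper - lower) / (1 + exp(-rate * (day - midpoint)))
}

# Band-model constants. Static absorption lobes sit at the pigment and O-H
# overtone bands seen in whole-egg transmittance (589, 643, 750, 970 nm);
# content-dependent lobes sit in the region where freshness-related features
# concentrate (700, 740, 870, 960 nm) plus a broad term so the overall mean
# transmittance decreases as S-ovalbumin content rises.
.gauss_lobe <- function(wl, center, width) exp(-((wl - center) / width)^2)

.baseline_shape <- function(wl) 0.35 + 0.65 * .gauss_lobe(wl, 730, 220)

.absorb_static <- function(wl) {
  0.45 * .gauss_lobe(wl, 589, 18) +
    0.35 * .gauss_lobe(wl, 643, 22) +
    0.30 * .gauss_lobe(wl, 750, 30) +
    0.55 * .gauss_lobe(wl, 970, 25)
}

.absorb_content <- function(wl) {
  0.55 * .gauss_lobe(wl, 700, 30) +
    0.45 * .gauss_lobe(wl, 740, 28) +
    0.50 * .gauss_lobe(wl, 870, 40) +
    0.40 * .gauss_lobe(wl, 960, 25) +
    0.25 * .gauss_lobe(wl, 800, 200)
}

#' Model transmittance spectrum for a given S-ovalbumin content
#'
#' Generates one transmittance spectrum under a Beer-Lambert-style model
#' \deqn{T(\lambda) = g\,B(\lambda)\,e^{-[a_0(\lambda) + c\,a_1(\lambda)]}
#'   + o + \epsilon(\lambda)}
#' where `B` is a smooth instrument baseline, `a0` holds static absorption
#' lobes (589, 643, 750, 970 nm), `a1` holds content-dependent lobes
#' (700, 740, 870, 960 nm and a broad background term), `g`/`o` are the
#' per-sample multiplicative/additive scatter that SNV is meant to remove,
#' and `eps` is iid Gaussian noise. Mean transmittance strictly decreases
#' with content.
#'
#' @param content S-ovalbumin fraction in \[0, 1\].
#' @param gain Multiplicative scatter factor (> 0).
#' @param offset Additive scatter offset.
#' @param noise_sd Per-band Gaussian noise SD (transmittance units).
#' @param wavelengths Wavelength vector in nm; defaults to the full
#'   478-band grid of [make_wavelength_grid()].
#' @param seed Optional integer seed for the noise draw.
#' @return Numeric transmittance vector, one value per wavelength.
#' @export
spectrum_model <- function(content, gain = 1, offset = 0, noise_sd = 0,
                           wavelengths = NULL, seed = NULL) {
  if (content < 0 || content > 1) {
    rlang::abort("`content` must lie in [0, 1].",
                 class = "ovaspec_domain_error")
  }
  if (gain <= 0) {
    rlang::abort("`gain` must be positive.", class = "ovaspec_domain_error")
  }
  wl <- wavelengths %||% make_wavelength_grid()$wavelength_nm
  clean <- gain * .baseline_shape(wl) *
    exp(-(.absorb_static(wl) + content * .absorb_content(wl))) + offset
  if (noise_sd > 0) {
    eps <- if (is.null(seed)) {
      stats::rnorm(length(wl), 0, noise_sd)
    } else {
      withr::with_seed(seed, stats::rnorm(length(wl), 0, noise_sd))
    }
    clean <- clean + eps
  }
  clean
}

#' Simulate the spectrophotometric S-ovalbumin assay
#'
#' The wet-chemistry reference assay heats an albumen suspension, measures
#' the absorbance of the soluble fraction before (`O_unheated`) and after
#' (`O_heated`) heating, and reports `100 * O_heated / O_unheated` percent.
#' Here `O_unheated` is drawn lognormal, `O_heated` is the true content
#' times `O_unheated` perturbed by relative noise `eta ~ N(0, cv)`, and the
#' ratio is clipped to \[0, 100\]%.
#'
#' @param true_content True S-ovalbumin fraction(s) in \[0, 1\].
#' @param cv Relative (coefficient-of-variation) assay noise; default 0.03
#'   is a configurable stand-in, the true assay error being unknown.
#' @param seed Optional integer seed.
#' @return Simulated assay readout(s) in percent.
#' @export
simulate_spectrophotometry <- function(true_content, cv = 0.03, seed = NULL) {
  if (any(true_content < 0 | true_content > 1)) {
    rlang::abort("`true_content` must lie in [0, 1].",
                 class = "ovaspec_domain_error")
  }
  if (cv < 0) {
    rlang::abort("`cv` must be non-negative.", class = "ovaspec_domain_error")
  }
  draw <- function() {
    n <- length(true_content)
    o_unheated <- stats::rlnorm(n, meanlog = log(0.8), sdlog = 0.15)
    eta <- if (cv > 0) stats::rnorm(n, 0, cv) else numeric(n)
    o_heated <- true_content * o_unheated * (1 + eta)
    pmin(pmax(100 * o_heated / o_unheated, 0), 100)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Storage-experiment design
#'
#' Describes the storage study layout: eggs measured after each of a set of
#' storage periods. The default reproduces an 18-eggs-per-day design over
#' days 0, 3, ..., 27 (180 eggs total).
#'
#' @param storage_days Strictly increasing non-negative integer days.
#' @param eggs_per_day Number of eggs measured per storage day (>= 1).
#' @param seed Integer seed controlling every random draw derived from the
#'   design.
#' @return A list of class `storage_design`.
#' @export
storage_design <- function(storage_days = seq(0L, 27L, by = 3L),
                           eggs_per_day = 18L, seed = 1L) {
  storage_days <- as.integer(storage_days)
  if (any(storage_days < 0) || is.unsorted(storage_days, strictly = TRUE)) {
    rlang::abort("`storage_days` must be strictly increasing and non-negative.",
                 class = "ovaspec_domain_error")
  }
  if (eggs_per_day < 1) {
    rlang::abort("`eggs_per_day` must be >= 1.",
                 class = "ovaspec_domain_error")
  }
  structure(
    list(storage_days = storage_days, eggs_per_day = as.integer(eggs_per_day),
         seed = as.integer(seed)),
    class = "storage_design"
  )
}

# Generator condition constants (see the methods vignette for rationale).
.ova_defaults <- list(
  content_jitter_sd = 0.04,   # egg-to-egg spread around the storage curve
  content_clip = c(0.10, 0.95),
  gain_sd = 0.08, gain_clip = c(0.8, 1.2),
  offset_sd = 0.01,
  reference_cv = 0.03,
  pixel_field_sd = 0.02,      # smooth within-egg content heterogeneity
  spectral_noise_sd = 0.005,  # per-band transmittance noise on mean spectra
  sensor_noise_sd = 2,        # raw-count sensor noise
  background_t = 0.005,       # background transmittance level
  white_level = 3000, dark_level = 100
)

#' Ground-truth table for a storage design
#'
#' Draws per-egg true S-ovalbumin content around [storage_curve()], per-egg
#' multiplicative/additive scatter, and the noisy spectrophotometric
#' reference readout. Fully determined by the design and its seed.
#'
#' @param design A [storage_design()].
#' @param reference_cv Relative noise of the simulated reference assay.
#' @return Tibble with columns `sample_id`, `storage_day`, `true_content`
#'   (fraction), `reference_content` (percent), `scatter_gain`,
#'   `scatter_offset`, and `egg_seed` (per-egg cube-rendering seed).
#' @export
generate_ground_truth <- function(design,
                                  reference_cv = .ova_defaults$reference_cv) {
  stopifnot(inherits(design, "storage_design"))
  days <- rep(design$storage_days, each = design$eggs_per_day)
  n <- length(days)
  d <- .ova_defaults
  withr::with_seed(design$seed, {
    truth <- storage_curve(days) + stats::rnorm(n, 0, d$content_jitter_sd)
    truth <- pmin(pmax(truth, d$content_clip[1]), d$content_clip[2])
    gain <- pmin(pmax(stats::rnorm(n, 1, d$gain_sd), d$gain_clip[1]),
                 d$gain_clip[2])
    offset <- stats::rnorm(n, 0, d$offset_sd)
    ref <- simulate_spectrophotometry(truth, cv = reference_cv)
  })
  tibble::tibble(
    sample_id = sprintf("egg_%03d", seq_len(n)),
    storage_day = days,
    true_content = truth,
    reference_content = ref,
    scatter_gain = gain,
    scatter_offset = offset,
    egg_seed = (design$seed + 7919L * seq_len(n)) %% 2147483647L
  )
}

#' White and dark reference cubes
#'
#' The white reference emulates a ~99% transmittance standard board
#' (smooth spectral profile near the full sensor range); the dark reference
#' emulates the covered-lens dark current. Both carry per-voxel sensor
#' noise.
#'
#' @param cube_shape Integer `c(lines, samples)`, each >= 8.
#' @param wavelengths Wavelength vector (defaults to the 478-band grid).
#' @param seed Integer seed.
#' @return List with `white` and `dark` [hypercube()] objects plus the
#'   noiseless `white_profile` / `dark_level` used to render raw egg cubes.
#' @export
generate_reference_cubes <- function(cube_shape = c(64L, 64L),
                                     wavelengths = NULL, seed = 1L) {
  wl <- wavelengths %||% make_wavelength_grid()$wavelength_nm
  .check_cube_shape(cube_shape)
  d <- .ova_defaults
  w0 <- d$white_level * (0.55 + 0.45 * .gauss_lobe(wl, 720, 260))
  npx <- prod(cube_shape[1:2])
  nb <- length(wl)
  withr::with_seed(seed, {
    white <- array(rep(w0, each = npx) + stats::rnorm(npx * nb, 0, 5),
                   dim = c(cube_shape[1], cube_shape[2], nb))
    dark <- array(d$dark_level + stats::rnorm(npx * nb, 0, d$sensor_noise_sd),
                  dim = c(cube_shape[1], cube_shape[2], nb))
  })
  list(white = hypercube(white, wl), dark = hypercube(dark, wl),
       white_profile = w0, dark_level = d$dark_level)
}

.check_cube_shape <- function(cube_shape) {
  if (length(cube_shape) != 2 || any(cube_shape < 8)) {
    rlang::abort("`cube_shape` must be two dimensions, each >= 8.",
                 class = "ovaspec_domain_error")
  }
}

# Smooth 2-D random field (sum of low-frequency cosine modes) rescaled to a
# target SD; drives within-egg content heterogeneity so chemical maps are
# visibly uneven while the per-egg mean stays at the egg's true content.
.smooth_field <- function(lines, samples, sd_target, n_modes = 6L) {
  rr <- matrix(rep(seq_len(lines), samples), lines, samples)
  cc <- matrix(rep(seq_len(samples), each = lines), lines, samples)
  field <- matrix(0, lines, samples)
  for (k in seq_len(n_modes)) {
    amp <- stats::rnorm(1)
    fx <- stats::runif(1, 0.5, 1.5)
    fy <- stats::runif(1, 0.5, 1.5)
    ph <- stats::runif(1, 0, 2 * pi)
    field <- field + amp * cos(2 * pi * (fx * rr / lines + fy * cc / samples) + ph)
  }
  s <- stats::sd(as.vector(field))
  if (s > 0) field <- field * (sd_target / s)
  field - mean(field)
}

#' Render one raw egg hypercube
#'
#' Renders an elliptical egg region on a dark background. Each in-egg pixel
#' carries the egg's transmittance spectrum at the egg content plus a
#' smooth spatial content perturbation; transmittance is converted to raw
#' sensor counts against the supplied white/dark profiles and sensor noise
#' is added. Deterministic given the truth row's `egg_seed`.
#'
#' @param truth_row One row of the tibble from [generate_ground_truth()].
#' @param cube_shape Integer `c(lines, samples)`.
#' @param wavelengths Wavelength vector (defaults to the 478-band grid).
#' @param white_profile,dark_level Noiseless reference profiles, as
#'   returned by [generate_reference_cubes()].
#' @return List with `cube` (raw-count [hypercube()]) and `mask` (logical
#'   lines x samples matrix of the planted egg region).
#' @export
generate_egg_cube <- function(truth_row, cube_shape = c(64L, 64L),
                              wavelengths = NULL,
                              white_profile = NULL, dark_level = NULL) {
  wl <- wavelengths %||% make_wavelength_grid()$wavelength_nm
  .check_cube_shape(cube_shape)
  d <- .ova_defaults
  if (is.null(white_profile)) {
    white_profile <- d$white_level * (0.55 + 0.45 * .gauss_lobe(wl, 720, 260))
  }
  dark_level <- dark_level %||% d$dark_level
  lines <- cube_shape[1]; samples <- cube_shape[2]
  npx <- lines * samples
  nb <- length(wl)
  base_vec <- truth_row$scatter_gain * .baseline_shape(wl) *
    exp(-.absorb_static(wl))
  a1 <- .absorb_content(wl)
  withr::with_seed(truth_row$egg_seed, {
    cx <- lines / 2 + stats::runif(1, -2, 2)
    cy <- samples / 2 + stats::runif(1, -2, 2)
    ax <- 0.32 * lines * (1 + stats::runif(1, -0.08, 0.08))
    ay <- 0.40 * samples * (1 + stats::runif(1, -0.08, 0.08))
    rr <- matrix(rep(seq_len(lines), samples), lines, samples)
    cc <- matrix(rep(seq_len(samples), each = lines), lines, samples)
    mask <- ((rr - cx) / ax)^2 + ((cc - cy) / ay)^2 <= 1
    field <- .smooth_field(lines, samples, d$pixel_field_sd)
    content_px <- pmin(pmax(truth_row$true_content + field[mask], 0), 1)
    tmat <- matrix(d$background_t, npx, nb)
    tmat[as.vector(mask), ] <- exp(-outer(content_px, a1)) *
      rep(base_vec, each = sum(mask)) + truth_row$scatter_offset
    raw <- tmat * rep(white_profile - dark_level, each = npx) + dark_level +
      stats::rnorm(npx * nb, 0, d$sensor_noise_sd)
  })
  list(cube = hypercube(array(raw, dim = c(lines, samples, nb)), wl),
       mask = mask)
}

#' Generate a complete synthetic study
#'
#' Materialises every egg cube, the shared white/dark reference cubes and
#' the ground-truth table for a storage design. All outputs are pure
#' functions of `(design, cube_shape)`. Intended for desk-scale designs:
#' the full 180-egg default occupies gigabytes if held at once, for which
#' [run_pipeline()] streams cubes instead.
#'
#' @inheritParams generate_ground_truth
#' @param cube_shape Integer `c(lines, samples)`, each >= 8.
#' @return List with `cubes` (list of raw [hypercube()]s), `masks` (planted
#'   egg masks), `white`, `dark`, and `truth`.
#' @export
generate_dataset <- function(design, cube_shape = c(64L, 64L)) {
  truth <- generate_ground_truth(design)
  wl <- make_wavelength_grid()$wavelength_nm
  refs <- generate_reference_cubes(cube_shape, wl,
                                   seed = (design$seed + 104729L) %% 2147483647L)
  rendered <- purrr::map(seq_len(nrow(truth)), function(i) {
    generate_egg_cube(truth[i, ], cube_shape, wl,
                      refs$white_profile, refs$dark_level)
  })
  list(
    cubes = purrr::map(rendered, "cube"),
    masks = purrr::map(rendered, "mask"),
    white = refs$white,
    dark = refs$dark,
    truth = truth
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
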