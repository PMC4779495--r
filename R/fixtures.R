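## Synthetic fixtures: Gaussian-band absorption curves at the canonical NIR
## band centers of water, protein and fat; composition sets spanning a wide
## fat range; noisy "measured" spectra; and raw DV cubes with white/dark
## references.  These emulate the structure of measured meat data so every
## pipeline stage can be exercised without any external dataset.

#' Canonical NIR absorption bands of the major meat chromophores
#'
#' Gaussian band parameters (center nm, sigma nm, amplitude per cm) at the
#' band centers classically assigned in the NIR: water O-H bands at 970,
#' 1440 and 1920 nm; fat C-H overtone/combination bands at 930, 1040, 1200,
#' 1715, 1750, 2125, 2300 and 2340 nm; protein N-H bands at 1187, 1510,
#' 1690 and 2265 nm.  Amplitudes are order-of-magnitude realistic for the
#' pure constituents (water dominated by the strong 1440/1920 bands) but are
#' synthetic: matching any published optical-constant dataset in absolute
#' magnitude is not the goal.
#'
#' @param chromophore `"water"`, `"protein"` or `"fat"`.
#' @return data frame with columns `center`, `width`, `amplitude`.
#' @export
default_bands <- function(chromophore = c("water", "protein", "fat")) {
  chromophore <- match.arg(chromophore)
  switch(chromophore,
    water = data.frame(
      center    = c(970, 1440, 1920),
      width     = c(35, 55, 70),
      amplitude = c(0.45, 28, 115)),
    fat = data.frame(
      center    = c(930, 1040, 1200, 1715, 1750, 2125, 2300, 2340),
      width     = c(18, 20, 35, 22, 20, 30, 22, 18),
      amplitude = c(0.6, 0.25, 1.3, 6.0, 4.5, 3.5, 6.5, 5.5)),
    protein = data.frame(
      center    = c(1187, 1510, 1690, 2265),
      width     = c(30, 45, 35, 40),
      amplitude = c(0.6, 3.5, 2.0, 4.0)))
}

#' Build a Gaussian-band absorption curve
#'
#' mu_a(lambda) = baseline + sum_j amplitude_j * exp(-(lambda - center_j)^2 /
#' (2 width_j^2)), evaluated on `grid`.
#'
#' @param bands data frame with columns `center`, `width`, `amplitude`
#'   (all positive; nm, nm, per cm).  May have zero rows.
#' @param baseline constant baseline absorption, per cm, nonnegative.
#' @param grid wavelength grid, nm.
#' @param chromophore label attached to the curve.
#' @return an [absorption_curve].
#' @export
make_absorption_curve <- function(bands, baseline = 0, grid = nir_grid(),
                                  chromophore = "other") {
  grid <- check_grid(grid)
  if (nrow(bands) > 0) {
    if (!all(c("center", "width", "amplitude") %in% names(bands)))
      stop_data("bands needs columns center, width, amplitude")
    if (any(bands$center <= 0) || any(bands$width <= 0) || any(bands$amplitude <= 0))
      stop_data("band centers, widths and amplitudes must be positive")
  }
  if (baseline < 0) stop_data("baseline must be nonnegative")
  v <- rep(baseline, length(grid))
  for (j in seq_len(nrow(bands)))
    v <- v + bands$amplitude[j] *
      exp(-(grid - bands$center[j])^2 / (2 * bands$width[j]^2))
  absorption_curve(grid, v, chromophore)
}

#' Default synthetic chromophore curve set
#'
#' The three [default_bands()] curves on one grid, with small baselines,
#' as a named list ready for [mix_absorption()], [model1_matrix()] and
#' [simulate_model2()].
#'
#' @param grid wavelength grid, nm (default 900--2400 nm at 5 nm).
#' @return named list of [absorption_curve]s (`water`, `protein`, `fat`).
#' @export
make_fixture_curves <- function(grid = nir_grid()) {
  list(water   = make_absorption_curve(default_bands("water"), 0.10, grid, "water"),
       protein = make_absorption_curve(default_bands("protein"), 0.05, grid, "protein"),
       fat     = make_absorption_curve(default_bands("fat"), 0.05, grid, "fat"))
}

#' Generate a composition set over a fat range
#'
#' For each requested fat mass fraction, draws a protein fraction as a
#' uniform share of the non-fat remainder capped at `protein_max` (meat
#' protein rarely exceeds ~22%), and assigns the rest to water.  The default
#' fat fractions span 2.49%--80.60%, the spread of fat contents in typical
#' minced-meat calibration sets.
#'
#' @param fat_fractions fat mass fractions in \[0, 1).
#' @param protein_max cap on the protein mass fraction (default 0.22).
#' @param seed integer seed (the draw is bit-reproducible given the seed).
#' @return list of [composition] objects.
#' @export
make_composition_set <- function(fat_fractions = c(0.0249, 0.0563, 0.143,
                                                   0.353, 0.6056, 0.8060),
                                 protein_max = 0.22, seed = 1) {
  if (anyNA(fat_fractions) || any(fat_fractions < 0) || any(fat_fractions >= 1))
    stop_data("fat fractions must lie in [0, 1)")
  set.seed(seed)
  u <- stats::runif(length(fat_fractions), 0.15, 0.25)
  out <- vector("list", length(fat_fractions))
  for (i in seq_along(fat_fractions)) {
    f <- fat_fractions[i]
    p <- min(protein_max, u[i] * (1 - f))
    w <- 1 - f - p
    out[[i]] <- composition(water = w, protein = p, fat = f)
  }
  names(out) <- sprintf("fat%05.2f", 100 * fat_fractions)
  out
}

#' Simulate a noisy measured spectrum
#'
#' Adds a constant baseline shift and i.i.d. Gaussian noise to a true
#' spectrum, emulating an instrument measurement.  Values are clamped to the
#' physical range of the spectrum kind (nonnegative for absorbance, \[0, 1\]
#' for reflectance/transmittance).
#'
#' @param true_spectrum a [spectrum].
#' @param noise_sd Gaussian noise standard deviation, >= 0, in the
#'   spectrum's units.
#' @param baseline_shift additive offset (default 0).
#' @param seed integer seed.
#' @return a [spectrum] of the same kind.
#' @export
make_measurement <- function(true_spectrum, noise_sd, baseline_shift = 0, seed = 1) {
  stopifnot(inherits(true_spectrum, "spectrum"))
  if (!(length(noise_sd) == 1L && noise_sd >= 0))
    stop_data("noise_sd must be a single nonnegative number")
  set.seed(seed)
  v <- true_spectrum$value + baseline_shift +
    stats::rnorm(length(true_spectrum$value), 0, noise_sd)
  v <- if (true_spectrum$kind %in% c("reflectance", "transmittance"))
    pmin(pmax(v, 0), 1) else pmax(v, 0)
  spectrum(true_spectrum$wavelength, v, true_spectrum$kind)
}

#' Synthesize raw DV cubes from a reflectance truth
#'
#' Produces the (sample, white, dark) trio a line-scan hyperspectral camera
#' would record for a scene of known reflectance: DV = round(dark + R *
#' (white - dark) + noise), clipped to the valid count range of the A/D
#' converter.  The white and dark reference cubes are generated at the same
#' levels (plus the same noise model).
#'
#' @param reflectance_truth a `reflectance_cube` (see [reflectance_cube()]).
#' @param bit_depth A/D bit depth (default 12).
#' @param white_level,dark_level mean counts of the white and dark
#'   references; `dark_level < white_level <= 2^bit_depth - 1`.
#' @param noise_sd Gaussian count noise SD (default 0).
#' @param seed integer seed.
#' @return list of three [dv_cube]s: `sample`, `white`, `dark`.
#' @export
make_dv_cube <- function(reflectance_truth, bit_depth = 12,
                         white_level = 3800, dark_level = 120,
                         noise_sd = 0, seed = 1) {
  if (!(inherits(reflectance_truth, "hyper_cube") &&
        reflectance_truth$kind == "reflectance"))
    stop_data("reflectance_truth must be a reflectance cube")
  mx <- 2^bit_depth - 1
  if (!(dark_level >= 0 && dark_level < white_level && white_level <= mx))
    stop_data("need 0 <= dark_level < white_level <= %d; got dark=%g, white=%g",
              mx, dark_level, white_level)
  set.seed(seed)
  d <- dim(reflectance_truth$data)
  g <- reflectance_truth$wavelength
  mk <- function(mean_counts) {
    raw <- round(mean_counts + stats::rnorm(prod(d), 0, noise_sd))
    dv_cube(array(pmin(pmax(raw, 0), mx), d), g, bit_depth)
  }
  list(sample = mk(dark_level + reflectance_truth$data * (white_level - dark_level)),
       white = mk(array(white_level, d)),
       dark = mk(array(dark_level, d)))
}
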