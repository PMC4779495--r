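## Chromophore optics: refractive-index dispersion, absorption mixing,
## Beer-Lambert absorbance, absorbance/transmittance conversion.

#' Empirical refractive-index dispersion model
#'
#' Two-term Cauchy-type dispersion for water-dominated biological tissue,
#' n(lambda) = c0 + c2/lambda^2 + c4/lambda^4 with lambda in nm.  The default
#' coefficients reproduce reported muscle indices of 1.38 at 632.8 nm and
#' 1.37 at 1341.4 nm (to two decimals).
#'
#' @param c0,c2,c4 dispersion coefficients (lambda in nm).
#' @return object of class `"ri_model"`.
#' @export
ri_model <- function(c0 = 1.3696, c2 = 3916.8, c4 = 2558.8) {
  m <- structure(list(c0 = c0, c2 = c2, c4 = c4), class = "ri_model")
  n_nir <- refractive_index(nir_grid(), m)
  if (any(n_nir <= 1))
    stop_domain("dispersion coefficients give n <= 1 inside the NIR grid")
  m
}

#' Refractive index at given wavelengths
#'
#' @param lambda wavelengths in nm, all positive.
#' @param model a [ri_model]; defaults to the tissue dispersion model.
#' @return dimensionless refractive indices, same length as `lambda`.
#' @examples
#' refractive_index(c(632.8, 1341.4))   # ~1.38, ~1.37
#' @export
refractive_index <- function(lambda, model = ri_model()) {
  if (anyNA(lambda) || any(lambda <= 0))
    stop_domain("wavelengths must be positive (nm)")
  model$c0 + model$c2 / lambda^2 + model$c4 / lambda^4
}

#' Mix chromophore absorption curves by mass fraction
#'
#' The bulk absorption coefficient of a homogeneous composite sample is the
#' mass-fraction-weighted sum of its chromophores' absorption coefficients:
#' mu_a(lambda) = f_w mu_w + f_p mu_p + f_f mu_f.  All curves must share one
#' wavelength grid; no silent resampling is performed.
#'
#' @param curves named list with elements `water`, `protein`, `fat`, each an
#'   [absorption_curve] (or spectrum of kind `absorption_coefficient`) on a
#'   common grid.
#' @param comp a [composition].
#' @return [spectrum] of kind `"absorption_coefficient"` (per cm).
#' @export
mix_absorption <- function(curves, comp) {
  stopifnot(inherits(comp, "composition"))
  need <- c("water", "protein", "fat")
  if (!all(need %in% names(curves)))
    stop_data("curves must be a named list with elements: %s",
              paste(need, collapse = ", "))
  for (nm in need) {
    if (!inherits(curves[[nm]], "spectrum") ||
        curves[[nm]]$kind != "absorption_coefficient")
      stop_data("curves$%s must be a spectrum of kind absorption_coefficient", nm)
  }
  g <- curves$water$wavelength
  require_same_grid(g, curves$protein$wavelength, "water and protein curves")
  require_same_grid(g, curves$fat$wavelength, "water and fat curves")
  mu <- comp$water * curves$water$value +
    comp$protein * curves$protein$value +
    comp$fat * curves$fat$value
  spectrum(g, mu, "absorption_coefficient")
}

#' Beer-Lambert absorbance from an absorption coefficient
#'
#' A(lambda) = log10(e) * mu_a(lambda) * l, i.e. the decadic absorbance of a
#' non-scattering path of length `l` through a medium with absorption
#' coefficient `mu_a` (the familiar printed constant 0.4343 is log10 e).
#'
#' @param mu_a [spectrum] of kind `"absorption_coefficient"` (per cm).
#' @param l path length, cm, positive.
#' @return [spectrum] of kind `"absorbance"`.
#' @export
beer_lambert_absorbance <- function(mu_a, l = 1) {
  stopifnot(inherits(mu_a, "spectrum"))
  if (mu_a$kind != "absorption_coefficient")
    stop_data("input must be an absorption-coefficient spectrum, not %s", mu_a$kind)
  if (!is.numeric(l) || length(l) != 1L || !is.finite(l) || l <= 0)
    stop_domain("path length must be a single positive number (cm); got %s",
                deparse(l))
  spectrum(mu_a$wavelength, log10(exp(1)) * mu_a$value * l, "absorbance")
}

#' Convert between absorbance and transmittance
#'
#' A = log10(1/T) and its inverse T = 10^(-A).  Accepts bare numeric vectors
#' or a [spectrum] (whose kind must match `from` and is switched on return).
#'
#' @param x numeric vector or [spectrum].
#' @param from direction of the conversion: the quantity `x` currently holds.
#' @return converted values (or converted spectrum).
#' @examples
#' absorbance_transmittance(0.5, from = "transmittance")  # 0.30103
#' @export
absorbance_transmittance <- function(x, from = c("transmittance", "absorbance")) {
  from <- match.arg(from)
  if (inherits(x, "spectrum")) {
    if (x$kind != from)
      stop_data("spectrum kind is %s but from=%s", x$kind, from)
    to <- if (from == "transmittance") "absorbance" else "transmittance"
    return(spectrum(x$wavelength, absorbance_transmittance(x$value, from), to))
  }
  if (from == "transmittance") {
    if (any(x <= 0) || any(x > 1 + 1e-12))
      stop_domain("transmittance must lie in (0, 1]")
    log10(1 / x)
  } else {
    if (any(x < 0))
      stop_domain("absorbance must be nonnegative")
    10^(-x)
  }
}
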