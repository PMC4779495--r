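## Core spectral containers: wavelength grids, spectra, absorption curves,
## compositions.  All wavelengths are nanometres everywhere in the package;
## absorption coefficients are per centimetre.

SPECTRUM_KINDS <- c("absorbance", "reflectance", "transmittance",
                    "absorption_coefficient")

check_grid <- function(wavelength, what = "wavelength grid") {
  if (length(wavelength) == 0L)
    stop_data("%s is empty", what)
  if (anyNA(wavelength) || !is.numeric(wavelength))
    stop_data("%s must be numeric with no missing values", what)
  if (any(wavelength <= 0))
    stop_data("%s must be strictly positive (nm)", what)
  if (any(diff(wavelength) <= 0)) {
    i <- which(diff(wavelength) <= 0)[1L] + 1L
    stop_data("%s must be strictly increasing; violation at position %d (%.6g after %.6g)",
              what, i, wavelength[i], wavelength[i - 1L])
  }
  as.numeric(wavelength)
}

same_grid <- function(g1, g2) {
  length(g1) == length(g2) && isTRUE(all.equal(g1, g2, tolerance = 1e-9))
}

require_same_grid <- function(g1, g2, what = "spectra") {
  if (!same_grid(g1, g2))
    stop_grid("%s are not on a shared wavelength grid (no silent resampling; use resample())",
              what)
  invisible(TRUE)
}

#' Construct a regular NIR wavelength grid
#'
#' Convenience constructor for the working grids used throughout: the
#' spectroscopy grid 900--2400 nm and the hyperspectral grid 950--1650 nm,
#' both at 5 nm steps by default.
#'
#' @param from,to grid limits in nm.
#' @param by step in nm.
#' @return numeric vector of strictly increasing wavelengths (nm).
#' @examples
#' g <- nir_grid()            # 900..2400 nm, 5 nm
#' h <- nir_grid(950, 1650)   # hyperspectral working range
#' @export
nir_grid <- function(from = 900, to = 2400, by = 5) {
  if (!(from > 0 && to > from && by > 0))
    stop_domain("invalid grid specification: from=%g, to=%g, by=%g", from, to, by)
  check_grid(seq(from, to, by = by))
}

#' Wavelength-indexed spectrum
#'
#' A spectrum is a vector of per-wavelength values tagged with the physical
#' quantity it holds (`kind`).  Reflectance and transmittance must lie in
#' \[0, 1\]; absorbance and absorption coefficients must be nonnegative.
#'
#' @param wavelength strictly increasing wavelengths, nm.
#' @param value per-wavelength values, same length as `wavelength`.
#' @param kind one of `"absorbance"`, `"reflectance"`, `"transmittance"`,
#'   `"absorption_coefficient"`.
#' @return an object of class `"spectrum"`.
#' @examples
#' s <- spectrum(c(1000, 1100, 1200), c(0.2, 0.5, 0.3), "absorbance")
#' print(s)
#' @export
spectrum <- function(wavelength, value, kind) {
  kind <- match.arg(kind, SPECTRUM_KINDS)
  wavelength <- check_grid(wavelength)
  if (length(value) != length(wavelength))
    stop_data("value length (%d) does not match grid length (%d)",
              length(value), length(wavelength))
  if (anyNA(value))
    stop_data("spectrum values contain NA")
  value <- as.numeric(value)
  tol <- 1e-9
  if (kind %in% c("reflectance", "transmittance")) {
    if (any(value < -tol) || any(value > 1 + tol))
      stop_data("%s values must lie in [0, 1]; range is [%.6g, %.6g]",
                kind, min(value), max(value))
    value <- pmin(pmax(value, 0), 1)
  } else {
    if (any(value < -tol))
      stop_data("%s values must be nonnegative; minimum is %.6g", kind, min(value))
    value <- pmax(value, 0)
  }
  structure(list(wavelength = wavelength, value = value, kind = kind),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> kind=%s, %d bands, %g-%g nm\n",
              x$kind, length(x$wavelength), min(x$wavelength), max(x$wavelength)))
  cat(sprintf("  value range: [%.6g, %.6g]\n", min(x$value), max(x$value)))
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelength, value = x$value)
}

#' @export
length.spectrum <- function(x) length(x$wavelength)

#' @export
plot.spectrum <- function(x, ..., xlab = "wavelength (nm)", ylab = x$kind,
                          type = "l") {
  graphics::plot(x$wavelength, x$value, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Per-chromophore absorption-coefficient curve
#'
#' An absorption curve is a spectrum of kind `"absorption_coefficient"`
#' carrying the identity of the chromophore it belongs to (water, protein,
#' fat, or another label).
#'
#' @param wavelength strictly increasing wavelengths, nm.
#' @param mu_a absorption coefficients, per cm, nonnegative.
#' @param chromophore label, e.g. `"water"`.
#' @return an object of classes `"absorption_curve"` and `"spectrum"`.
#' @export
absorption_curve <- function(wavelength, mu_a, chromophore = "other") {
  s <- spectrum(wavelength, mu_a, "absorption_coefficient")
  s$chromophore <- as.character(chromophore)[1L]
  class(s) <- c("absorption_curve", class(s))
  s
}

#' @export
print.absorption_curve <- function(x, ...) {
  cat(sprintf("<absorption curve> chromophore=%s\n", x$chromophore))
  NextMethod()
}

#' Sample composition as mass fractions
#'
#' Mass fractions of the three major NIR chromophores.  Each fraction must be
#' in \[0, 1\] and the total must be positive and at most 1 (the remainder is
#' non-absorbing in the NIR working range).
#'
#' @param water,protein,fat mass fractions (dimensionless).
#' @return an object of class `"composition"`.
#' @examples
#' composition(water = 0.70, protein = 0.20, fat = 0.10)
#' @export
composition <- function(water, protein, fat) {
  f <- c(water = water, protein = protein, fat = fat)
  if (anyNA(f) || !is.numeric(f) || length(f) != 3L)
    stop_data("composition requires three numeric mass fractions")
  if (any(f < 0) || any(f > 1))
    stop_data("mass fractions must each lie in [0, 1]; got (%.4g, %.4g, %.4g)",
              f[1], f[2], f[3])
  s <- sum(f)
  if (s <= 0 || s > 1 + 1e-12)
    stop_data("total mass fraction must lie in (0, 1]; got %.6g", s)
  structure(as.list(f), class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat(sprintf("<composition> water=%.4f protein=%.4f fat=%.4f (sum %.4f)\n",
              x$water, x$protein, x$fat, x$water + x$protein + x$fat))
  invisible(x)
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Interpolates the spectrum onto `target`.  The default is piecewise-linear
#' interpolation; natural cubic splines are available via `method = "spline"`.
#' Extrapolation outside the source range is refused.
#'
#' @param spec a [spectrum].
#' @param target new wavelength grid, nm, within the source range.
#' @param method `"linear"` (default) or `"spline"`.
#' @return a [spectrum] of the same kind on `target`.
#' @export
resample <- function(spec, target, method = c("linear", "spline")) {
  stopifnot(inherits(spec, "spectrum"))
  method <- match.arg(method)
  target <- check_grid(target, "target grid")
  if (min(target) < min(spec$wavelength) - 1e-9 ||
      max(target) > max(spec$wavelength) + 1e-9)
    stop_domain("target grid [%g, %g] nm extends beyond the source range [%g, %g] nm (extrapolation refused)",
                min(target), max(target), min(spec$wavelength), max(spec$wavelength))
  v <- if (method == "linear") {
    stats::approx(spec$wavelength, spec$value, xout = target)$y
  } else {
    stats::spline(spec$wavelength, spec$value, xout = target, method = "natural")$y
  }
  if (spec$kind %in% c("reflectance", "transmittance")) v <- pmin(pmax(v, 0), 1)
  else v <- pmax(v, 0)
  spectrum(target, v, spec$kind)
}

#' Restrict a spectrum to a wavelength window
#'
#' Drops all bands outside `[lo, hi]` (inclusive).  Used to trim the noisy
#' spectral edges of hyperspectral measurements, e.g. keeping 950--1650 nm
#' of a 900--1700 nm scan.
#'
#' @param spec a [spectrum].
#' @param lo,hi window limits in nm, `lo < hi`.
#' @return the trimmed [spectrum].
#' @export
trim_range <- function(spec, lo, hi) {
  stopifnot(inherits(spec, "spectrum"))
  if (!(lo < hi))
    stop_domain("trim window requires lo < hi; got [%g, %g]", lo, hi)
  keep <- spec$wavelength >= lo & spec$wavelength <= hi
  if (!any(keep))
    stop_data("trim window [%g, %g] nm contains no grid points", lo, hi)
  spectrum(spec$wavelength[keep], spec$value[keep], spec$kind)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (so 1.375 -> 1.38 at two
#' decimals), the convention used when comparing computed refractive indices
#' with values printed to two decimal places.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
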