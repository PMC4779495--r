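## Hyperspectral calibration: raw digital values (DV) -> reflectance via
## white/dark references, reflectance -> pseudoabsorbance, ROI mean spectra.
## Cubes are (row, col, band) arrays; line-scan references recorded as a
## single row broadcast across all sample rows.

#' Hyperspectral cube containers
#'
#' A cube is a (row, col, band) array with a wavelength grid along the band
#' axis.  `dv_cube` holds raw integer camera counts bounded by the bit depth
#' (default 12-bit: counts 0--4095); `reflectance_cube` holds calibrated
#' reflectance in \[0, 1\]; kind `"absorbance"` cubes hold pseudoabsorbance.
#'
#' @param data numeric (row, col, band) array.
#' @param wavelength band wavelengths, nm; length must match `dim(data)[3]`.
#' @param bit_depth A/D converter bit depth (default 12).
#' @return an object of class `"hyper_cube"` with fields `data`,
#'   `wavelength`, `kind`, and for DV cubes `bit_depth`.
#' @export
dv_cube <- function(data, wavelength, bit_depth = 12) {
  cube_new(data, wavelength, "dv", bit_depth)
}

#' @rdname dv_cube
#' @export
reflectance_cube <- function(data, wavelength) {
  cube_new(data, wavelength, "reflectance")
}

cube_new <- function(data, wavelength, kind, bit_depth = NULL) {
  if (!(is.array(data) && length(dim(data)) == 3L))
    stop_data("cube data must be a 3-d (row, col, band) array")
  wavelength <- check_grid(wavelength, "cube band grid")
  if (dim(data)[3] != length(wavelength))
    stop_data("cube has %d bands but grid has %d wavelengths",
              dim(data)[3], length(wavelength))
  if (anyNA(data)) stop_data("cube data contain NA")
  if (kind == "dv") {
    if (!(length(bit_depth) == 1L && bit_depth >= 1 && bit_depth == as.integer(bit_depth)))
      stop_data("bit_depth must be a positive integer")
    mx <- 2^bit_depth - 1
    if (any(data < 0) || any(data > mx))
      stop_data("digital values must lie in [0, %d] for a %d-bit sensor; range is [%g, %g]",
                mx, bit_depth, min(data), max(data))
    if (any(data != round(data)))
      stop_data("digital values must be integer counts")
  } else if (kind == "reflectance") {
    if (any(data < -1e-9) || any(data > 1 + 1e-9))
      stop_data("reflectance values must lie in [0, 1]; range is [%g, %g]",
                min(data), max(data))
    data[] <- pmin(pmax(data, 0), 1)
  } else if (kind == "absorbance") {
    if (any(data < -1e-9)) stop_data("absorbance values must be nonnegative")
    data[] <- pmax(data, 0)
  } else stop_data("unknown cube kind: %s", kind)
  structure(list(data = data, wavelength = wavelength, kind = kind,
                 bit_depth = if (kind == "dv") as.integer(bit_depth) else NULL),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyper cube> kind=%s, %d x %d pixels, %d bands (%g-%g nm)%s\n",
              x$kind, d[1], d[2], d[3], min(x$wavelength), max(x$wavelength),
              if (!is.null(x$bit_depth)) sprintf(", %d-bit", x$bit_depth) else ""))
  invisible(x)
}

## Broadcast a 1-row line-scan reference cube to `rows` rows.
broadcast_rows <- function(cube, rows) {
  d <- dim(cube$data)
  if (d[1] == rows) return(cube$data)
  if (d[1] == 1L) {
    arr <- cube$data[rep(1L, rows), , , drop = FALSE]
    return(arr)
  }
  stop_data("reference cube has %d rows; expected 1 (broadcast) or %d", d[1], rows)
}

#' Flat-field calibration of raw digital values to reflectance
#'
#' R = (DV_sample - DV_dark) / (DV_white - DV_dark), elementwise.  Any common
#' per-band gain/offset of the sensor cancels exactly, which is why raw
#' counts calibrate directly to reflectance.  Values outside \[0, 1\]
#' (routine under sensor noise) are clipped, counted, and reported via a
#' message and the `"n_clipped"` attribute.  References recorded as a single
#' row are broadcast across all sample rows.
#'
#' @param sample,white,dark [dv_cube]s on one grid with compatible
#'   dimensions.
#' @return a `reflectance_cube` with attribute `n_clipped`.
#' @export
calibrate <- function(sample, white, dark) {
  for (cc in list(sample, white, dark))
    if (!(inherits(cc, "hyper_cube") && cc$kind == "dv"))
      stop_data("calibrate() expects dv cubes")
  require_same_grid(sample$wavelength, white$wavelength, "sample and white cubes")
  require_same_grid(sample$wavelength, dark$wavelength, "sample and dark cubes")
  d <- dim(sample$data)
  W <- broadcast_rows(white, d[1])
  D <- broadcast_rows(dark, d[1])
  if (!all(dim(W)[2:3] == d[2:3]) || !all(dim(D)[2:3] == d[2:3]))
    stop_data("cube dimensions differ between sample and references")
  den <- W - D
  bad <- which(den <= 0)
  if (length(bad) > 0) {
    ix <- arrayInd(bad[1], d)
    stop_data("white <= dark at pixel (row %d, col %d, band %d); cannot calibrate",
              ix[1], ix[2], ix[3])
  }
  R <- (sample$data - D) / den
  n_clip <- sum(R < 0 | R > 1)
  if (n_clip > 0)
    message(sprintf("calibrate: clipped %d of %d reflectance values to [0, 1]",
                    n_clip, length(R)))
  R[] <- pmin(pmax(R, 0), 1)
  out <- reflectance_cube(R, sample$wavelength)
  attr(out, "n_clipped") <- n_clip
  out
}

#' Pseudoabsorbance of a reflectance cube
#'
#' A = log10(1 / max(R, floor)) per voxel; the floor guards zero reflectance
#' and any flooring is reported.
#'
#' @param cube a `reflectance_cube`.
#' @param floor reflectance floor (default 1e-6).
#' @return a `hyper_cube` of kind `"absorbance"`.
#' @export
pseudoabsorbance <- function(cube, floor = 1e-6) {
  if (!(inherits(cube, "hyper_cube") && cube$kind == "reflectance"))
    stop_data("pseudoabsorbance() expects a reflectance cube")
  n_floored <- sum(cube$data < floor)
  if (n_floored > 0)
    message(sprintf("pseudoabsorbance: floored %d of %d reflectance values at %g",
                    n_floored, length(cube$data), floor))
  A <- log10(1 / pmax(cube$data, floor))
  cube_new(A, cube$wavelength, "absorbance")
}

#' ROI mean spectrum of a cube
#'
#' Per-band arithmetic mean over the pixels selected by `mask`.
#'
#' @param cube a reflectance or absorbance `hyper_cube`.
#' @param mask logical (or 0/1) row-by-col matrix selecting pixels; `NULL`
#'   selects every pixel.
#' @return a [spectrum] of the cube's kind.
#' @export
mean_spectrum <- function(cube, mask = NULL) {
  if (!(inherits(cube, "hyper_cube") && cube$kind %in% c("reflectance", "absorbance")))
    stop_data("mean_spectrum() expects a reflectance or absorbance cube (calibrate first)")
  d <- dim(cube$data)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (!(is.matrix(mask) && all(dim(mask) == d[1:2])))
    stop_data("mask must be a %d x %d matrix", d[1], d[2])
  sel <- as.vector(mask != 0)
  if (!any(sel)) stop_data("mask selects no pixels")
  m <- matrix(cube$data, d[1] * d[2], d[3])
  spectrum(cube$wavelength, colMeans(m[sel, , drop = FALSE]), cube$kind)
}
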