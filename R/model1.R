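## Model 1: Beer-Lambert linear mixing in matrix form, plus the exponential
## absorption-to-absorbance map calibrated on a single reference sample.
## In reflectance mode the geometric path length is unmeasurable, so the
## matrix product is computed with an effective unit path (l = 1) and the
## fitted exponential map absorbs the unknown scale.

#' Model 1 absorbance matrix
#'
#' Computes log10(e) * l * M %*% F, where M is the (wavelength x 3) matrix of
#' chromophore absorption coefficients and F the (3 x samples) matrix of mass
#' fractions: each column is the Beer-Lambert absorbance-scale spectrum of one
#' sample.  The default path length l = 1 leaves the columns equal to
#' 0.4343 * mu_a on an effective unit path (see Details).
#'
#' @details In reflectance-mode spectroscopy the light path through the
#'   sample cannot be measured, so `l` here is a unitless effective path kept
#'   at its default 1; absolute absorbance scale is subsequently supplied by
#'   the exponential map of [fit_exp_map()].
#'
#' @param curves named list of `water`, `protein`, `fat` absorption curves on
#'   a shared grid (see [mix_absorption]).
#' @param compositions a [composition] or a list of them.
#' @param l effective path length multiplier (default 1).
#' @return numeric matrix (wavelengths x samples) with wavelength rownames.
#' @export
model1_matrix <- function(curves, compositions, l = 1) {
  if (inherits(compositions, "composition")) compositions <- list(compositions)
  if (length(compositions) < 1L)
    stop_data("at least one composition is required")
  if (!all(vapply(compositions, inherits, logical(1), "composition")))
    stop_data("compositions must be composition objects")
  if (!is.numeric(l) || length(l) != 1L || l <= 0)
    stop_domain("path length must be a single positive number")
  need <- c("water", "protein", "fat")
  if (!all(need %in% names(curves)))
    stop_data("curves must be a named list with elements: %s",
              paste(need, collapse = ", "))
  g <- curves$water$wavelength
  require_same_grid(g, curves$protein$wavelength, "water and protein curves")
  require_same_grid(g, curves$fat$wavelength, "water and fat curves")
  M <- cbind(water = curves$water$value,
             protein = curves$protein$value,
             fat = curves$fat$value)
  F <- vapply(compositions, function(cc) c(cc$water, cc$protein, cc$fat),
              numeric(3))
  A <- log10(exp(1)) * l * (M %*% F)
  rownames(A) <- g
  colnames(A) <- names(compositions) %||% paste0("sample", seq_along(compositions))
  A
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the exponential absorption-to-absorbance map
#'
#' With the path length unknown, measured absorbance saturates as the bulk
#' absorption coefficient grows.  This fits the saturating exponential
#' A = a (1 - exp(-b mu_a)) (or the unbounded growth form A = a exp(b mu_a))
#' to one designated calibration sample by ordinary least squares over all
#' wavelengths, pairing the sample's computed mu_a with its measured A.
#'
#' @param mu_a_calib [spectrum] of kind `absorption_coefficient`: bulk
#'   absorption coefficient of the calibration sample (from
#'   [mix_absorption]).
#' @param A_measured [spectrum] of kind `absorbance`: measured absorbance of
#'   the same sample, same grid.
#' @param form `"saturating"` (default) for A = a(1 - exp(-b mu)), or
#'   `"growing"` for A = a exp(b mu).
#' @return an object of class `"exp_map"` with components `a`, `b`, `form`,
#'   `residual_norm`, `fitted`, `data`, supporting `coef`, `predict`,
#'   `fitted`, `residuals`, `print` and `plot`.
#' @seealso [apply_exp_map()] to transform new absorption spectra.
#' @export
fit_exp_map <- function(mu_a_calib, A_measured, form = c("saturating", "growing")) {
  form <- match.arg(form)
  stopifnot(inherits(mu_a_calib, "spectrum"), inherits(A_measured, "spectrum"))
  if (mu_a_calib$kind != "absorption_coefficient")
    stop_data("mu_a_calib must be an absorption-coefficient spectrum")
  if (A_measured$kind != "absorbance")
    stop_data("A_measured must be an absorbance spectrum")
  require_same_grid(mu_a_calib$wavelength, A_measured$wavelength,
                    "calibration spectra")
  mu <- mu_a_calib$value
  A <- A_measured$value
  if (any(A < 0)) stop_data("measured absorbance must be nonnegative")
  if (length(unique(signif(mu, 12))) < 3L)
    stop_fit("calibration needs at least 3 distinct absorption-coefficient values")
  start <- if (form == "saturating") {
    list(a = max(max(A), 1e-6), b = 1 / max(stats::median(mu), 1e-12))
  } else {
    lf <- stats::lm(log(pmax(A, 1e-12)) ~ mu)
    list(a = exp(unname(stats::coef(lf)[1])), b = max(unname(stats::coef(lf)[2]), 1e-6))
  }
  fml <- if (form == "saturating") A ~ a * (1 - exp(-b * mu)) else A ~ a * exp(b * mu)
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = data.frame(mu = mu, A = A), start = start,
                      lower = c(a = 1e-12, b = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop_fit("exponential-map fit failed to converge: %s",
                                 conditionMessage(e)))
  cf <- stats::coef(fit)
  obj <- structure(list(
    a = unname(cf["a"]), b = unname(cf["b"]), form = form,
    residual_norm = sqrt(sum(stats::resid(fit)^2)),
    fitted = as.numeric(stats::fitted(fit)),
    data = data.frame(mu = mu, A = A, wavelength_nm = mu_a_calib$wavelength),
    n = length(mu)), class = "exp_map")
  obj
}

#' @export
print.exp_map <- function(x, ...) {
  f <- if (x$form == "saturating") "A = a * (1 - exp(-b * mu_a))"
       else "A = a * exp(b * mu_a)"
  cat("Exponential absorption-to-absorbance map\n")
  cat(sprintf("  form: %s\n", f))
  cat(sprintf("  a = %.6g, b = %.6g (per cm^-1)\n", x$a, x$b))
  cat(sprintf("  calibration: %d wavelengths, residual norm %.4g\n",
              x$n, x$residual_norm))
  invisible(x)
}

#' @export
coef.exp_map <- function(object, ...) c(a = object$a, b = object$b)

#' @export
fitted.exp_map <- function(object, ...) object$fitted

#' @export
residuals.exp_map <- function(object, ...) object$data$A - object$fitted

#' @rdname fit_exp_map
#' @param object a fitted `exp_map`.
#' @param newdata numeric vector of absorption coefficients (per cm) or a
#'   [spectrum] of kind `absorption_coefficient`; defaults to the calibration
#'   data.
#' @param ... unused.
#' @export
predict.exp_map <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (inherits(newdata, "spectrum")) return(apply_exp_map(newdata, object)$value)
  mu <- as.numeric(newdata)
  if (any(mu < 0)) stop_domain("absorption coefficients must be nonnegative")
  if (object$form == "saturating") object$a * (1 - exp(-object$b * mu))
  else object$a * exp(object$b * mu)
}

#' @export
plot.exp_map <- function(x, ...) {
  o <- order(x$data$mu)
  graphics::plot(x$data$mu[o], x$data$A[o], pch = 16, cex = 0.5,
                 xlab = expression(mu[a] ~ (cm^-1)), ylab = "absorbance A", ...)
  graphics::lines(x$data$mu[o], x$fitted[o], col = 2, lwd = 2)
  invisible(x)
}

#' Apply a fitted exponential map to an absorption spectrum
#'
#' Transforms a bulk absorption-coefficient spectrum into the absorbance
#' scale using a previously fitted [exp_map][fit_exp_map].  The map is
#' monotone increasing in mu_a; for the saturating form it is bounded above
#' by `a`.
#'
#' @param mu_a [spectrum] of kind `absorption_coefficient`.
#' @param params a fitted `exp_map` object, or a list with `a`, `b`, `form`.
#' @return [spectrum] of kind `"absorbance"`.
#' @export
apply_exp_map <- function(mu_a, params) {
  stopifnot(inherits(mu_a, "spectrum"))
  if (mu_a$kind != "absorption_coefficient")
    stop_data("input must be an absorption-coefficient spectrum")
  a <- params$a; b <- params$b
  form <- params$form %||% "saturating"
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0)
    stop_domain("exp-map parameters must be positive and finite")
  v <- if (form == "saturating") a * (1 - exp(-b * mu_a$value))
       else a * exp(b * mu_a$value)
  spectrum(mu_a$wavelength, v, "absorbance")
}

#' Read/write exponential-map parameters as key=value text
#'
#' Persists the two fitted parameters (and the functional form) in a plain
#' two-plus-one-line `key=value` file.
#'
#' @param params an `exp_map` object or list with `a`, `b`, `form`.
#' @param path file path.
#' @return `read_exp_map` returns a list with `a`, `b`, `form` usable by
#'   [apply_exp_map()]; `write_exp_map` returns `path` invisibly.
#' @export
write_exp_map <- function(params, path) {
  writeLines(c(sprintf("a=%.17g", params$a),
               sprintf("b=%.17g", params$b),
               sprintf("form=%s", params$form %||% "saturating")), path)
  invisible(path)
}

#' @rdname write_exp_map
#' @export
read_exp_map <- function(path) {
  if (!file.exists(path)) stop_data("exp-map file not found: %s", path)
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  if (!all(c("a", "b") %in% keys))
    stop_data("exp-map file %s must contain keys a and b", path)
  list(a = as.numeric(vals[keys == "a"][1]),
       b = as.numeric(vals[keys == "b"][1]),
       form = if ("form" %in% keys) vals[keys == "form"][1] else "saturating")
}
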