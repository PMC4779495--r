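## Model-evaluation statistics for (measured, approximated) spectrum pairs:
## RMSE, ratio of performance to deviation (RPD) with its three-category
## robustness rule, and Willmott's index of agreement d.

spec_pair <- function(pred, meas) {
  stopifnot(inherits(pred, "spectrum"), inherits(meas, "spectrum"))
  require_same_grid(pred$wavelength, meas$wavelength, "predicted and measured spectra")
  list(p = pred$value, m = meas$value, n = length(meas$value))
}

#' Root-mean-square error between spectra
#'
#' RMSE = sqrt(sum((pred_k - meas_k)^2) / n) over the shared grid (the `n`
#' denominator, as the error formula states it).
#'
#' @param pred,meas [spectrum] objects on one grid.
#' @return nonnegative scalar in the spectra's units.
#' @export
rmse <- function(pred, meas) {
  d <- spec_pair(pred, meas)
  sqrt(mean((d$p - d$m)^2))
}

#' Ratio of performance to deviation
#'
#' RPD = SD(measured) / RMSE, with the sample standard deviation (n - 1
#' denominator) of the measured spectrum.  A perfect prediction (RMSE = 0 on
#' a non-constant measurement) returns `Inf`; a constant measured spectrum
#' has no defined RPD and raises a degeneracy error.
#'
#' @param pred,meas [spectrum] objects on one grid, at least 2 bands.
#' @return positive scalar (possibly `Inf`).
#' @export
rpd <- function(pred, meas) {
  d <- spec_pair(pred, meas)
  if (d$n < 2L) stop_domain("RPD requires at least 2 wavelengths")
  s <- stats::sd(d$m)
  if (s == 0)
    stop_degenerate("measured spectrum is constant; RPD is undefined")
  e <- rmse(pred, meas)
  if (e == 0) return(Inf)
  s / e
}

#' Robustness category of an RPD value
#'
#' RPD above 2.0 marks a robust model, values in the inclusive range
#' 1.4--2.0 an intermediate model that can possibly be improved, and values
#' below 1.4 an unreliable model with no predictive ability.
#'
#' @param rpd positive RPD value(s); `Inf` is robust.
#' @return character vector: `"robust"`, `"intermediate"` or `"unreliable"`.
#' @examples
#' classify_rpd(c(6.144, 1.432, 1.105))
#' @export
classify_rpd <- function(rpd) {
  if (anyNA(rpd) || any(rpd <= 0))
    stop_domain("RPD must be positive")
  ifelse(rpd > 2, "robust", ifelse(rpd >= 1.4, "intermediate", "unreliable"))
}

#' Willmott's index of agreement
#'
#' d = 1 - sum((pred_k - meas_k)^2) /
#'          sum((|pred_k - mbar| + |meas_k - mbar|)^2),
#' with mbar the mean of the measured spectrum (the standard convention for
#' both deviation terms).  d is bounded in \[0, 1\]: 1 for perfect agreement,
#' 0 for a predictor stuck at the measured mean.
#'
#' @param pred,meas [spectrum] objects on one grid.
#' @return scalar in \[0, 1\].
#' @export
agreement_d <- function(pred, meas) {
  d <- spec_pair(pred, meas)
  mbar <- mean(d$m)
  den <- sum((abs(d$p - mbar) + abs(d$m - mbar))^2)
  if (den == 0)
    stop_degenerate("both spectra are constant at the measured mean; d is undefined")
  min(max(1 - sum((d$p - d$m)^2) / den, 0), 1)
}

#' Evaluate a (predicted, measured) spectrum pair
#'
#' Bundles [rmse()], [rpd()] with its robustness category, and
#' [agreement_d()] into one report.
#'
#' @param pred,meas [spectrum] objects on one grid.
#' @return object of class `"eval_report"` with fields `rmse`, `rpd`, `d`,
#'   `category`, `n`.
#' @examples
#' g <- nir_grid()
#' truth <- spectrum(g, 1 + sin(g / 200), "absorbance")
#' noisy <- make_measurement(truth, noise_sd = 0.02, seed = 1)
#' evaluate(truth, noisy)
#' @export
evaluate <- function(pred, meas) {
  d <- spec_pair(pred, meas)
  r <- rmse(pred, meas)
  q <- rpd(pred, meas)
  structure(list(rmse = r, rpd = q, d = agreement_d(pred, meas),
                 category = classify_rpd(q), n = d$n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Spectrum approximation report\n")
  cat(sprintf("  n wavelengths: %d\n", x$n))
  cat(sprintf("  RMSE: %.4g\n", x$rmse))
  cat(sprintf("  RPD:  %s  (%s)\n",
              if (is.finite(x$rpd)) sprintf("%.4g", x$rpd) else "Inf", x$category))
  cat(sprintf("  Willmott d: %.4g\n", x$d))
  invisible(x)
}

#' Read/write an evaluation report as JSON
#'
#' An infinite RPD (perfect prediction) is serialized as the string
#' `"Inf"` and parsed back to `Inf`.
#'
#' @param report an `eval_report`.
#' @param path JSON file path.
#' @return `read_eval_report` returns the `eval_report`; `write_eval_report`
#'   returns `path` invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  x <- unclass(report)
  if (!is.finite(x$rpd)) x$rpd <- "Inf"
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  if (!file.exists(path)) stop_data("report file not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(x$rpd, "Inf")) x$rpd <- Inf
  structure(list(rmse = as.numeric(x$rmse), rpd = as.numeric(x$rpd),
                 d = as.numeric(x$d), category = as.character(x$category),
                 n = as.integer(x$n)),
            class = "eval_report")
}
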