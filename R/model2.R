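## Model 2: N-layer plate (Stokes) radiative-transfer model.  A sample is
## treated as a pile of N identical homogeneous plates separated by air gaps.
## Per wavelength: the tissue refractive index n sets the Fresnel interface
## behaviour (through the averaged transmissivity tav), the bulk absorption
## coefficient sets the diffuse transmission theta of one plate through the
## exponential-integral relation, a single plate's reflectance/transmittance
## follow in closed form, and the Stokes system stacks N plates.

#' Plate-model structural and illumination parameters
#'
#' @param N number of elementary layers, integer >= 1 (default 25).
#' @param alpha incidence angle in degrees, in (0, 90\] (default 45).
#' @param s per-layer optical-depth scale multiplying the bulk absorption
#'   coefficient (dimensionless effective layer thickness in cm-equivalents;
#'   default 1, i.e. mu_a in per-cm is used directly as the per-layer optical
#'   depth).
#' @return object of class `"plate_params"`.
#' @export
plate_params <- function(N = 25, alpha = 45, s = 1) {
  if (!(length(N) == 1L && N >= 1 && N == as.integer(N)))
    stop_domain("N must be a positive integer")
  if (!(length(alpha) == 1L && alpha > 0 && alpha <= 90))
    stop_domain("alpha must lie in (0, 90] degrees")
  if (!(length(s) == 1L && is.finite(s) && s > 0))
    stop_domain("optical-depth scale s must be positive")
  structure(list(N = as.integer(N), alpha = alpha, s = s),
            class = "plate_params")
}

#' @export
print.plate_params <- function(x, ...) {
  cat(sprintf("<plate params> N=%d layers, alpha=%g deg, s=%g\n",
              x$N, x$alpha, x$s))
  invisible(x)
}

## Unpolarized Fresnel transmittance air -> medium of index n at incidence
## theta_i (radians).  theta_i vector x n vector -> matrix.
fresnel_transmittance <- function(theta_i, n) {
  si <- sin(theta_i); ci <- cos(theta_i)
  st <- outer(si, 1 / n)                      # Snell: sin(theta_t)
  ct <- sqrt(pmax(1 - st^2, 0))
  ci_m <- matrix(ci, length(theta_i), length(n))
  n_m <- matrix(n, length(theta_i), length(n), byrow = TRUE)
  rs <- (ci_m - n_m * ct) / (ci_m + n_m * ct)
  rp <- (n_m * ci_m - ct) / (n_m * ci_m + ct)
  1 - (rs^2 + rp^2) / 2
}

#' Average transmissivity of a plane dielectric surface
#'
#' Transmissivity of an air/medium interface averaged over all incidence
#' directions within the cone \[0, alpha\] and over both polarizations,
#' weighted by projected solid angle:
#' tav(alpha, n) = (1/sin^2 alpha) * integral_0^alpha T(theta) sin(2 theta) d theta,
#' with T the unpolarized Fresnel transmittance.  Evaluated by 64-node
#' Gauss-Legendre quadrature; this quadrature is the reference definition
#' used throughout the plate model.
#'
#' @param alpha incidence cone half-angle, degrees, in (0, 90\].
#' @param n refractive index (vectorized), n >= 1.
#' @return averaged transmissivity in (0, 1\], same length as `n`.
#' @examples
#' tav(90, 1.45)
#' tav(45, refractive_index(nir_grid()))[1:3]
#' @export
tav <- function(alpha, n) {
  if (!(length(alpha) == 1L && is.finite(alpha) && alpha > 0 && alpha <= 90))
    stop_domain("alpha must lie in (0, 90] degrees")
  if (anyNA(n) || any(n < 1))
    stop_domain("refractive index must be >= 1")
  out <- numeric(length(n))
  one <- abs(n - 1) < .Machine$double.eps   # index-matched: exactly 1
  out[one] <- 1
  if (any(!one)) {
    a <- alpha * pi / 180
    gl <- pracma::gaussLegendre(64, 0, a)
    Tm <- fresnel_transmittance(gl$x, n[!one])
    out[!one] <- as.numeric(crossprod(gl$w * sin(2 * gl$x), Tm)) / sin(a)^2
  }
  out
}

#' Diffuse transmission of one absorbing plate
#'
#' Fraction of an isotropic diffuse flux transmitted through a single
#' absorbing plate of optical depth `k`:
#' theta(k) = (1 - k) exp(-k) + k^2 E1(k),
#' where E1 is the first exponential integral.  Equivalently
#' theta(k) = 2 * integral_0^1 mu exp(-k/mu) d mu.  theta(0) = 1 by
#' continuous extension; theta is strictly decreasing in k.
#'
#' @param k per-layer optical depth, dimensionless, k >= 0 (vectorized).
#' @return transmission coefficient in (0, 1\].
#' @examples
#' theta_from_mu(c(0, 1, 5))
#' @export
theta_from_mu <- function(k) {
  if (anyNA(k) || any(k < 0))
    stop_domain("optical depth k must be nonnegative")
  out <- numeric(length(k))
  z <- k == 0
  out[z] <- 1
  if (any(!z)) {
    kk <- k[!z]
    out[!z] <- (1 - kk) * exp(-kk) + kk^2 * pracma::expint_E1(kk)
  }
  pmin(pmax(out, 0), 1)
}

#' Reflectance and transmittance of one elementary layer
#'
#' Closed-form single-plate quantities of the plate model.  With
#' t_a = tav(alpha, n), t_90 = tav(90, n) and D = n^4 - theta^2 (n^2 - t_90)^2:
#' rho_alpha = 1 - t_a + t_a t_90 theta^2 (n^2 - t_90) / D,
#' tau_alpha = t_a t_90 n^2 theta / D, x = t_a / t_90, y = 1 - x,
#' rho_90 = (rho_alpha - y)/x, tau_90 = tau_alpha / x.
#' These are identical to composing the interface quantities
#' r12 = 1 - t_a, t12 = t_a, t21 = t_90/n^2, r21 = 1 - t21 with internal
#' transmission theta through the multiple-reflection geometric series.
#'
#' @param theta per-plate diffuse transmission in \[0, 1\] (vectorized).
#' @param n refractive index, >= 1 (vectorized, recycled against theta).
#' @param alpha incidence angle, degrees.
#' @return object of class `"layer_rt"`: list of vectors `rho_alpha`,
#'   `tau_alpha`, `rho_90`, `tau_90`, `x`, `y`.
#' @export
layer_rt <- function(theta, n, alpha = 45) {
  if (anyNA(theta) || any(theta < 0) || any(theta > 1 + 1e-12))
    stop_domain("theta must lie in [0, 1]")
  if (anyNA(n) || any(n < 1))
    stop_domain("refractive index must be >= 1")
  m <- max(length(theta), length(n))
  theta <- rep_len(pmin(theta, 1), m)
  n <- rep_len(n, m)
  t_a <- tav(alpha, n)
  t_90 <- tav(90, n)
  D <- n^4 - theta^2 * (n^2 - t_90)^2        # >= n^4 - n^2(n^2-t90) > 0
  rho_a <- 1 - t_a + t_a * t_90 * theta^2 * (n^2 - t_90) / D
  tau_a <- t_a * t_90 * n^2 * theta / D
  x <- t_a / t_90
  y <- 1 - x
  rho_90 <- (rho_a - y) / x
  tau_90 <- tau_a / x
  clamp01 <- function(v, what) {
    if (any(v < -1e-9) || any(v > 1 + 1e-9))
      stop_domain("plate quantity %s left [0, 1]: range [%.6g, %.6g]",
                  what, min(v), max(v))
    pmin(pmax(v, 0), 1)
  }
  structure(list(rho_alpha = clamp01(rho_a, "rho_alpha"),
                 tau_alpha = clamp01(tau_a, "tau_alpha"),
                 rho_90 = clamp01(rho_90, "rho_90"),
                 tau_90 = clamp01(tau_90, "tau_90"),
                 x = x, y = y),
            class = "layer_rt")
}

#' Stokes closed form for N stacked identical layers
#'
#' Total reflectance and transmittance of N identical plates from the
#' single-plate normal-incidence quantities (rho_90, tau_90), via the Stokes
#' homogeneous system: with
#' delta = sqrt((tau^2 - rho^2 - 1)^2 - 4 rho^2),
#' a = (1 + rho^2 - tau^2 + delta) / (2 rho),
#' b = (1 - rho^2 + tau^2 + delta) / (2 tau),
#' R_N,90 = (b^N - b^-N) / (a b^N - a^-1 b^-N),
#' T_N,90 = (a - a^-1) / (a b^N - a^-1 b^-N),
#' then R_N,alpha = x R_N,90 + y and T_N,alpha = x T_N,90.
#' The ratios are evaluated with numerator and denominator rescaled by b^-N,
#' so no overflow occurs even for very large N.  Limit branches: rho_90 = 0
#' gives (R, T) = (0, tau^N); tau_90 = 0 gives (rho_90, 0); the conservative
#' case rho_90 + tau_90 = 1 (zero absorption) gives
#' R_N = N rho / (1 + (N-1) rho), T_N = 1 - R_N.
#'
#' @param layer a [layer_rt] object (vectorized over wavelengths).
#' @param N number of layers, integer >= 1.
#' @return object of class `"stokes_rt"`: list of vectors `R_N_90`, `T_N_90`,
#'   `R_N_alpha`, `T_N_alpha`.
#' @export
stokes_stack <- function(layer, N) {
  stopifnot(inherits(layer, "layer_rt"))
  if (!(length(N) == 1L && N >= 1 && N == as.integer(N)))
    stop_domain("N must be a positive integer")
  rho <- layer$rho_90
  tau <- layer$tau_90
  m <- length(rho)
  R90 <- numeric(m); T90 <- numeric(m)
  eps <- 1e-12
  cons <- (1 - (rho + tau)) < 1e-12 & rho > eps & tau > eps
  zr <- rho <= eps & !cons
  zt <- tau <= eps & !cons
  gen <- !(cons | zr | zt)

  R90[zr] <- 0
  T90[zr] <- tau[zr]^N
  R90[zt] <- rho[zt]
  T90[zt] <- 0
  if (any(cons)) {
    rc <- rho[cons]
    R90[cons] <- N * rc / (1 + (N - 1) * rc)
    T90[cons] <- 1 - R90[cons]
  }
  if (any(gen)) {
    r <- rho[gen]; t <- tau[gen]
    disc <- (t^2 - r^2 - 1)^2 - 4 * r^2
    if (any(disc < -1e-10))
      stop_domain("negative discriminant in the Stokes system (rho=%.4g, tau=%.4g)",
                  r[which(disc < -1e-10)[1]], t[which(disc < -1e-10)[1]])
    delta <- sqrt(pmax(disc, 0))
    a <- (1 + r^2 - t^2 + delta) / (2 * r)
    b <- (1 - r^2 + t^2 + delta) / (2 * t)
    binv2N <- b^(-2 * N)                      # b >= 1 when rho + tau <= 1
    den <- a - binv2N / a
    R90[gen] <- (1 - binv2N) / den
    T90[gen] <- (a - 1 / a) * b^(-N) / den
  }
  R90 <- pmin(pmax(R90, 0), 1)
  T90 <- pmin(pmax(T90, 0), 1)
  structure(list(R_N_90 = R90, T_N_90 = T90,
                 R_N_alpha = pmin(pmax(layer$x * R90 + layer$y, 0), 1),
                 T_N_alpha = pmin(pmax(layer$x * T90, 0), 1)),
            class = "stokes_rt")
}

#' Simulate a sample spectrum with the N-layer plate model
#'
#' Per wavelength the chain is: refractive index from the dispersion model;
#' bulk absorption coefficient from mass-fraction mixing of the chromophore
#' curves; per-plate optical depth k = s * mu_a; diffuse plate transmission
#' theta(k); single-plate reflectance/transmittance; Stokes N-layer stack;
#' pseudoabsorbance A = log10(1 / R_N,alpha).
#'
#' @param curves named list of `water`, `protein`, `fat` absorption curves on
#'   a shared grid.
#' @param comp a [composition].
#' @param params a [plate_params] (defaults: N = 25 layers, alpha = 45
#'   degrees, s = 1).
#' @param ri a [ri_model] for n(lambda).
#' @param floor reflectance floor applied before the log (default 1e-6); any
#'   flooring is reported via a warning.
#' @param keep_rt if `TRUE`, attach the per-wavelength intermediates (n, k,
#'   theta, rho_90, tau_90, R, T) as the `"intermediates"` attribute
#'   (a data frame).
#' @return [spectrum] of kind `"absorbance"`.
#' @examples
#' curves <- make_fixture_curves(nir_grid())
#' A <- simulate_model2(curves, composition(0.6, 0.2, 0.15))
#' @export
simulate_model2 <- function(curves, comp, params = plate_params(),
                            ri = ri_model(), floor = 1e-6, keep_rt = FALSE) {
  stopifnot(inherits(params, "plate_params"))
  mu <- mix_absorption(curves, comp)
  g <- mu$wavelength
  n <- refractive_index(g, ri)
  k <- params$s * mu$value
  theta <- theta_from_mu(k)
  lt <- layer_rt(theta, n, params$alpha)
  st <- stokes_stack(lt, params$N)
  R <- st$R_N_alpha
  n_floored <- sum(R < floor)
  if (n_floored > 0) {
    warning(sprintf("reflectance floored at %g for %d of %d wavelengths before log",
                    floor, n_floored, length(R)))
    R <- pmax(R, floor)
  }
  A <- spectrum(g, log10(1 / R), "absorbance")
  if (keep_rt)
    attr(A, "intermediates") <- data.frame(
      wavelength_nm = g, n = n, k = k, theta = theta,
      rho90 = lt$rho_90, tau90 = lt$tau_90,
      R = st$R_N_alpha, T = st$T_N_alpha, A = A$value)
  A
}
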