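## Independent oracles and small shared fixtures.

## Unpolarized Fresnel transmittance written independently of the package
## (scalar, explicit Snell + both polarizations).
oracle_fresnel_T <- function(theta_i, n) {
  st <- sin(theta_i) / n
  ct <- sqrt(1 - st^2)
  ci <- cos(theta_i)
  rs <- ((ci - n * ct) / (ci + n * ct))^2
  rp <- ((n * ci - ct) / (n * ci + ct))^2
  1 - (rs + rp) / 2
}

## Average transmissivity by adaptive quadrature (projected-solid-angle
## weighting over the cone [0, alpha]).
oracle_tav <- function(alpha_deg, n) {
  a <- alpha_deg * pi / 180
  stats::integrate(function(th) vapply(th, oracle_fresnel_T, numeric(1), n = n) *
                     sin(2 * th),
                   0, a, rel.tol = 1e-10)$value / sin(a)^2
}

## Diffuse plate transmission by quadrature of 2 * int_0^1 mu exp(-k/mu) dmu;
## substituting t = 1/mu gives the numerically friendlier equivalent
## 2 * int_1^Inf exp(-k t) / t^3 dt.
oracle_theta <- function(k) {
  ## factor out exp(-k) so the integrand stays O(1) even for large k
  2 * exp(-k) * stats::integrate(function(u) exp(-k * u) / (1 + u)^3, 0, Inf,
                                 rel.tol = 1e-10)$value
}

## Adding-doubling recursion: stack N identical layers one at a time.
oracle_adding_doubling <- function(rho, tau, N) {
  R <- rho; T <- tau
  if (N > 1) for (i in 2:N) {
    den <- 1 - rho * R
    T_new <- tau * T / den
    R <- rho + tau^2 * R / den
    T <- T_new
  }
  list(R = R, T = T)
}

## Tiny shared fixtures.
tiny_grid <- c(1000, 1100, 1200, 1300)

tiny_curves <- function(grid = tiny_grid) {
  list(water = absorption_curve(grid, c(2, 1, 3, 2), "water"),
       protein = absorption_curve(grid, c(1, 2, 1, 1), "protein"),
       fat = absorption_curve(grid, c(3, 1, 2, 4), "fat"))
}

## 2-row reflectance truth cube on a small band grid.
tiny_truth_cube <- function(rows = 4, cols = 5, grid = seq(950, 1650, 100)) {
  b <- length(grid)
  vals <- outer(seq_len(rows * cols) / (rows * cols + 1),
                seq(0.2, 0.8, length.out = b), function(p, q) 0.5 * p + 0.5 * q)
  reflectance_cube(array(vals, c(rows, cols, b)), grid)
}
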