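test_that("tav is exactly 1 for an index-matched interface and matches quadrature", {
  expect_identical(tav(45, 1), 1)
  expect_identical(tav(90, 1), 1)
  for (n in c(1.2, 1.45, 1.6))
    expect_equal(tav(90, n), oracle_tav(90, n), tolerance = 1e-8)
  expect_equal(tav(45, 1.4), oracle_tav(45, 1.4), tolerance = 1e-8)
  expect_error(tav(45, 0.9), class = "nirsim_domain_error")
  expect_error(tav(0, 1.4), class = "nirsim_domain_error")
  expect_error(tav(91, 1.4), class = "nirsim_domain_error")
})

test_that("tav strictly decreases as the refractive index grows", {
  ns <- seq(1, 1.6, by = 0.05)
  for (alpha in c(30, 45, 90)) {
    tv <- tav(alpha, ns)
    expect_true(all(diff(tv) < 0), label = sprintf("alpha = %g", alpha))
    expect_true(all(tv > 0 & tv <= 1))
  }
})

test_that("theta closed form equals the diffuse-flux quadrature oracle", {
  expect_identical(theta_from_mu(0), 1)                 # continuity branch
  expect_equal(round(theta_from_mu(1), 5), 0.21938)  # = E1(1), printed 5 s.f.
  expect_lt(theta_from_mu(50), 1e-10)                   # opaque limit
  ks <- c(1e-6, 1e-4, 0.01, 0.1, 0.5, 1, 2, 5, 10, 20)
  for (k in ks)
    expect_lt(abs(theta_from_mu(k) - oracle_theta(k)), 1e-8)
  ## strictly decreasing, bounded in (0, 1]
  th <- theta_from_mu(seq(0, 20, by = 0.1))
  expect_true(all(diff(th) < 0))
  expect_true(all(th > 0 & th <= 1))
  expect_error(theta_from_mu(-0.1), class = "nirsim_domain_error")
})

test_that("layer_rt limits: index-matched plate and opaque plate", {
  ## n = 1: no surface reflection, transmission is theta
  lt <- layer_rt(0.6, 1, 45)
  expect_equal(lt$rho_alpha, 0)
  expect_equal(lt$tau_alpha, 0.6)
  expect_equal(lt$rho_90, 0)
  expect_equal(lt$tau_90, 0.6)
  expect_equal(lt$x, 1)
  expect_equal(lt$y, 0)
  ## n = 1 and theta = 1 edge
  lt1 <- layer_rt(1, 1, 45)
  expect_equal(lt1$rho_alpha, 0)
  expect_equal(lt1$tau_alpha, 1)
  ## theta = 0: only the front surface reflects
  lt0 <- layer_rt(0, 1.4, 45)
  expect_equal(lt0$tau_alpha, 0)
  expect_equal(lt0$rho_alpha, 1 - tav(45, 1.4))
})

test_that("layer_rt equals the Fresnel interface-composition oracle", {
  for (n in c(1.2, 1.4, 1.6)) for (theta in c(0.1, 0.5, 0.9)) for (alpha in c(45, 60)) {
    t12 <- tav(alpha, n)
    t21 <- tav(90, n) / n^2
    r21 <- 1 - t21
    den <- 1 - r21^2 * theta^2
    rho_oracle <- (1 - t12) + t12 * t21 * r21 * theta^2 / den
    tau_oracle <- t12 * t21 * theta / den
    lt <- layer_rt(theta, n, alpha)
    expect_equal(lt$rho_alpha, rho_oracle, tolerance = 1e-10)
    expect_equal(lt$tau_alpha, tau_oracle, tolerance = 1e-10)
  }
})

test_that("single-plate quantities conserve energy and obey the x,y relations", {
  set.seed(7)
  theta <- runif(200)
  n <- runif(200, 1, 1.6)
  lt <- layer_rt(theta, n, 45)
  expect_true(all(lt$rho_alpha + lt$tau_alpha <= 1 + 1e-12))
  expect_true(all(lt$rho_90 + lt$tau_90 <= 1 + 1e-12))
  ## rho_alpha = x rho_90 + y and tau_alpha = x tau_90 by construction
  expect_equal(lt$rho_alpha, lt$x * lt$rho_90 + lt$y, tolerance = 1e-12)
  expect_equal(lt$tau_alpha, lt$x * lt$tau_90, tolerance = 1e-12)
})

test_that("Stokes closed form matches the adding-doubling recursion", {
  rhos <- c(0.02, 0.1, 0.2, 0.3)
  taus <- c(0.05, 0.2, 0.4, 0.6)
  for (rho in rhos) for (tau in taus) {
    if (rho + tau >= 1) next
    lt <- structure(list(rho_90 = rho, tau_90 = tau, x = 1, y = 0,
                         rho_alpha = rho, tau_alpha = tau), class = "layer_rt")
    for (N in c(1:5, 10, 25, 50)) {
      st <- stokes_stack(lt, N)
      or <- oracle_adding_doubling(rho, tau, N)
      expect_equal(st$R_N_90, or$R, tolerance = 1e-10,
                   label = sprintf("R rho=%g tau=%g N=%d", rho, tau, N))
      expect_equal(st$T_N_90, or$T, tolerance = 1e-10,
                   label = sprintf("T rho=%g tau=%g N=%d", rho, tau, N))
    }
  }
})

test_that("Stokes stack limit branches and N = 1 identity", {
  mk <- function(rho, tau) structure(list(rho_90 = rho, tau_90 = tau, x = 1, y = 0,
                                          rho_alpha = rho, tau_alpha = tau),
                                     class = "layer_rt")
  ## N = 1 returns the single-plate values exactly
  s1 <- stokes_stack(mk(0.23, 0.41), 1)
  expect_equal(s1$R_N_90, 0.23, tolerance = 1e-12)
  expect_equal(s1$T_N_90, 0.41, tolerance = 1e-12)
  ## non-reflecting stack: R = 0, T = tau^N
  s0 <- stokes_stack(mk(0, 0.6), 25)
  expect_equal(s0$R_N_90, 0)
  expect_equal(s0$T_N_90, 0.6^25, tolerance = 1e-15)
  ## opaque plates: T = 0, R = rho
  sT <- stokes_stack(mk(0.3, 0), 25)
  expect_equal(sT$T_N_90, 0)
  expect_equal(sT$R_N_90, 0.3, tolerance = 1e-12)
  ## conservative plates (rho + tau = 1) follow the N rho / (1 + (N-1) rho) law
  sc <- stokes_stack(mk(0.25, 0.75), 25)
  expect_equal(sc$R_N_90, 25 * 0.25 / (1 + 24 * 0.25), tolerance = 1e-12)
  expect_equal(sc$R_N_90 + sc$T_N_90, 1, tolerance = 1e-12)
  expect_equal(oracle_adding_doubling(0.25, 0.75, 25)$R, sc$R_N_90,
               tolerance = 1e-10)
})

test_that("Stokes stack is overflow-free at very large N and monotone in N", {
  lt <- structure(list(rho_90 = 0.2, tau_90 = 0.6, x = 1, y = 0,
                       rho_alpha = 0.2, tau_alpha = 0.6), class = "layer_rt")
  s_big <- stokes_stack(lt, 10000L)
  expect_true(is.finite(s_big$R_N_90) && is.finite(s_big$T_N_90))
  expect_true(s_big$R_N_90 >= 0 && s_big$R_N_90 <= 1)
  ## R_N increases with N towards the infinite-stack limit
  Rs <- vapply(c(1:10, 25, 50, 200), function(N) stokes_stack(lt, N)$R_N_90,
               numeric(1))
  expect_true(all(diff(Rs) >= -1e-14))
  expect_lte(s_big$R_N_90, 1)
  expect_gte(s_big$R_N_90, Rs[length(Rs)] - 1e-12)
})

test_that("energy is conserved through the full stack on fuzzed inputs", {
  set.seed(11)
  for (i in 1:100) {
    theta <- runif(1)
    n <- runif(1, 1, 1.6)
    alpha <- runif(1, 5, 90)
    N <- sample(1:50, 1)
    st <- stokes_stack(layer_rt(theta, n, alpha), N)
    expect_lte(st$R_N_alpha + st$T_N_alpha, 1 + 1e-10)
    expect_gte(st$R_N_alpha, 0)
    expect_gte(st$T_N_alpha, 0)
  }
})

test_that("simulate_model2 composes the per-wavelength chain", {
  curves <- tiny_curves()
  comp <- composition(0.5, 0.2, 0.3)
  params <- plate_params(N = 25, alpha = 45, s = 1)
  A <- simulate_model2(curves, comp, params, keep_rt = TRUE)
  rt <- attr(A, "intermediates")
  ## hand-compose the chain at the second wavelength
  i <- 2L
  mu_i <- 0.5 * curves$water$value[i] + 0.2 * curves$protein$value[i] +
    0.3 * curves$fat$value[i]
  n_i <- refractive_index(tiny_grid[i])
  th_i <- theta_from_mu(mu_i)
  lt_i <- layer_rt(th_i, n_i, 45)
  st_i <- stokes_stack(lt_i, 25)
  expect_equal(rt$k[i], mu_i, tolerance = 1e-12)
  expect_equal(rt$theta[i], th_i, tolerance = 1e-12)
  expect_equal(rt$R[i], st_i$R_N_alpha, tolerance = 1e-12)
  expect_equal(A$value[i], log10(1 / st_i$R_N_alpha), tolerance = 1e-12)
})

test_that("zero absorption gives an n-only flat reflectance; absorbance rises with fat", {
  g <- tiny_grid
  zero <- list(water = absorption_curve(g, rep(0, 4), "water"),
               protein = absorption_curve(g, rep(0, 4), "protein"),
               fat = absorption_curve(g, rep(0, 4), "fat"))
  A0 <- simulate_model2(zero, composition(0.6, 0.2, 0.1), keep_rt = TRUE)
  rt <- attr(A0, "intermediates")
  expect_equal(rt$theta, rep(1, 4))
  ## R varies only through n(lambda): nearly flat over this short range
  expect_lt(diff(range(rt$R)), 1e-3)
  expect_equal(rt$R + rt$T, rep(1, 4), tolerance = 1e-10)  # k = 0: lossless
  ## raising the fraction of an absorbing chromophore darkens the sample
  curves <- tiny_curves()
  fats <- seq(0.05, 0.6, by = 0.05)
  R_at_1 <- vapply(fats, function(f) {
    attr(simulate_model2(curves, composition(0.3, 0.1, f), keep_rt = TRUE),
         "intermediates")$R[1]
  }, numeric(1))
  expect_true(all(diff(R_at_1) < 0))
})

test_that("vanishing reflectance is floored with a warning, never silently", {
  g <- c(1000, 1100)
  huge <- list(water = absorption_curve(g, c(0.1, 0.1), "water"),
               protein = absorption_curve(g, c(0.1, 0.1), "protein"),
               fat = absorption_curve(g, c(0.1, 0.1), "fat"))
  ## an index-matched stack with strong absorption has no surface reflection:
  ## R collapses to 0 and must be floored
  ri1 <- structure(list(c0 = 1 + 1e-13, c2 = 0, c4 = 0), class = "ri_model")
  expect_warning(
    A <- simulate_model2(huge, composition(0.4, 0.3, 0.3),
                         plate_params(N = 25, alpha = 45, s = 2000), ri = ri1),
    "floored|floor")
  expect_true(all(is.finite(A$value)))
  expect_true(all(A$value <= log10(1 / 1e-6) + 1e-9))
})

test_that("plate_params validates its domain", {
  expect_error(plate_params(N = 0), class = "nirsim_domain_error")
  expect_error(plate_params(alpha = 0), class = "nirsim_domain_error")
  expect_error(plate_params(alpha = 95), class = "nirsim_domain_error")
  expect_error(plate_params(s = -1), class = "nirsim_domain_error")
  p <- plate_params()
  expect_identical(p$N, 25L)
  expect_identical(p$alpha, 45)
  expect_identical(p$s, 1)
})
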