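fl <- fluid_constants()

test_that("settling velocity sits at the harmonic junction of its asymptotes", {
  Rp <- (2850 - 1025) / 1025
  for (D in c(2e-5, 1e-4, 2e-4, 1e-3, 5e-3)) {
    stokes <- Rp * fl$g * D^2 / (18 * fl$nu)
    turb <- sqrt(Rp * fl$g * D / 0.75)
    w <- settling_velocity(D)
    expect_lt(w, min(stokes, turb))
    expect_gt(w, 0.5 * min(stokes, turb))
    expect_equal(w, 1 / (1 / stokes + 1 / turb), tolerance = 1e-12)
  }
  # Stokes limit dominates for fine grains
  D <- 5e-6
  expect_equal(settling_velocity(D), Rp * fl$g * D^2 / (18 * fl$nu),
               tolerance = 0.05)
  expect_lt(settling_velocity(1e-9), 1e-9)
  expect_equal(settling_velocity(2e-4, rho_s = 1025), 0)
  expect_error(settling_velocity(-1e-4), "> 0")
})

test_that("Shields number definition and Brownlie threshold behave", {
  sh0 <- shields_numbers(2e-4, 0)
  expect_equal(sh0$tau_star, 0)
  expect_lt(sh0$tau_star, sh0$tau_star_c)
  # monotone in u_star^2 and 1/D
  sh <- function(D, u) shields_numbers(D, u)$tau_star
  expect_equal(sh(2e-4, 0.2) / sh(2e-4, 0.1), 4)
  expect_equal(sh(1e-4, 0.1) / sh(2e-4, 0.1), 2)
  tc <- critical_shields(2e-4)
  expect_gt(tc, 0.02)
  expect_lt(tc, 0.06)
  expect_equal(critical_shields(2e-4, method = "constant", const = 0.03),
               0.03)
})

test_that("bedload layer scales with transport stage and is capped at the depth", {
  bl <- bedload_layer(2e-4, 0.05, 0.05)
  expect_equal(bl$H_b, 1.44 * 2e-4)
  bl2 <- bedload_layer(2e-4, 0.10, 0.05)
  expect_equal(bl2$H_b / bl$H_b, sqrt(2))
  expect_equal(bl2$U_b / bl$U_b, 2^0.56)
  shallow <- bedload_layer(2e-3, 3, 0.03, H = 0.002)
  expect_equal(shallow$H_b, 0.002)
  expect_error(bedload_layer(2e-4, 0.01, 0.05), "threshold")
})

test_that("suspension integral matches brute-force quadrature and its limits", {
  # adaptive quadrature vs a 1e5-point midpoint Riemann sum, 4 sig figs
  cases <- list(c(D = 2e-4, u = 0.05), c(D = 5e-4, u = 0.08),
                c(D = 1e-4, u = 0.3), c(D = 1e-3, u = 0.15))
  for (cs in cases) {
    D <- cs[["D"]]; u <- cs[["u"]]
    w_s <- settling_velocity(D)
    H <- 1; H_b <- 1.44 * D * 4
    chi <- suspension_integral_chi(D, u, H, H_b, w_s)
    z0 <- D / 30
    P <- w_s / (fl$kappa * u)
    U <- (u / fl$kappa) * (log(H / z0) - 1 + z0 / H)
    z <- H_b + (seq_len(1e5) - 0.5) * (H - H_b) / 1e5
    integ <- (u / fl$kappa) * log(z / z0) *
      (((H - z) / z) * (H_b / (H - H_b)))^P
    brute <- sum(integ) * (H - H_b) / 1e5 / (U * H)
    expect_equal(chi, brute, tolerance = 5e-4)
  }
  # P -> infinity: suspension collapses onto the bed
  expect_lt(suspension_integral_chi(2e-4, 1e-4, 1, 5e-3, 0.5), 1e-10)
  # P = 0: well-mixed, chi ~ 1 for H_b << H
  expect_equal(suspension_integral_chi(2e-4, 0.1, 1, 5e-3, 0), 1,
               tolerance = 0.02)
  expect_error(suspension_integral_chi(2e-4, 0.1, 1, 2, 0.01), "H_b")
})

test_that("viscous damping ramps the impact velocity with Stokes number", {
  # fine mud: fully damped
  expect_equal(impact_velocity(settling_velocity(2e-5), 2e-5), 0)
  # coarse grains: undamped
  w_s <- settling_velocity(5e-3)
  expect_gt(stokes_number(w_s, 5e-3), 75)
  expect_equal(impact_velocity(w_s, 5e-3), w_s)
  # ramp midpoint gives half the settling velocity
  mid <- 52.5  # (30 + 75)/2
  D <- 1e-3
  w <- mid * 9 * fl$rho_w * fl$nu / (2850 * D)  # invert St for w_s
  expect_equal(stokes_number(w, D), mid)
  expect_equal(impact_velocity(w, D), w / 2)
  expect_true(all(impact_velocity(w_s, 5e-3) <= w_s))
  expect_error(impact_velocity(0.1, 1e-3, St_low = 80, St_high = 75),
               "St_high")
})

test_that("transport flux obeys its zero conditions", {
  expect_equal(as.numeric(sediment_energy_flux(0.1, 2e-3, q = 0)), 0)
  # below threshold of motion
  expect_equal(as.numeric(sediment_energy_flux(0.001, 2e-3)), 0)
  # viscously damped fine grains, even when mobile
  d <- transport_derived(0.1, 5e-5)
  expect_true(d$mobile)
  expect_equal(d$w_i, 0)
  expect_equal(as.numeric(sediment_energy_flux(0.1, 5e-5)), 0)
})

test_that("flux is linear in supply and cubic in impact velocity", {
  d <- transport_derived(0.1, 2e-3)
  f1 <- as.numeric(sediment_energy_flux(0.1, 2e-3, q = 1e-5, derived = d))
  f2 <- as.numeric(sediment_energy_flux(0.1, 2e-3, q = 2e-5, derived = d))
  expect_equal(f2 / f1, 2, tolerance = 1e-12)
  d8 <- d
  d8$w_i <- 2 * d$w_i
  f8 <- as.numeric(sediment_energy_flux(0.1, 2e-3, q = 1e-5, derived = d8))
  expect_equal(f8 / f1, 8, tolerance = 1e-12)
})

test_that("derived quantities are pure functions of the flow state", {
  a <- transport_derived(0.12, 8e-4)
  b <- transport_derived(0.12, 8e-4)
  expect_identical(a, b)
  expect_true(a$w_i <= a$w_s)
  expect_true(a$H_b <= 1)
})

test_that("every shear-velocity column is zero below threshold, positive above (coarse grains)", {
  D <- 2e-3  # coarse enough to escape viscous damping
  u_axis <- seq(0.01, 0.4, length.out = 12)
  tc <- critical_shields(D)
  flux <- vapply(u_axis, function(u) {
    as.numeric(sediment_energy_flux(u, D))
  }, numeric(1))
  mobile <- vapply(u_axis, function(u) {
    shields_numbers(D, u)$tau_star >= tc
  }, logical(1))
  expect_true(any(mobile) && any(!mobile))
  expect_true(all(flux[!mobile] == 0))
  expect_true(all(flux[mobile] > 0))
})
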