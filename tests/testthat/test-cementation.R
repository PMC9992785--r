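test_that("specific surface area follows the inverse-diameter model", {
  expect_equal(specific_surface_area(1e-4), 5 / (2850 * 1e-4))
  kin1 <- mineral_kinetics(0.283, 0.113, 2.26, 0.1, 2850, 1)
  expect_equal(specific_surface_area(1 / 2850, kin1), 1)
  expect_equal(specific_surface_area(5e-5), 2 * specific_surface_area(1e-4))
  expect_equal(specific_surface_area("fine_sand"),
               specific_surface_area(1.25e-4))
  expect_equal(specific_surface_area(1e-4, sphere_factor = 6),
               6 * specific_surface_area(1e-4))
  expect_error(specific_surface_area(-1e-4), "> 0")
  expect_error(resolve_grain_size("pebble"), "unknown grain-size class")
})

test_that("precipitation volume rate follows the supersaturation power law", {
  expect_equal(precipitation_volume_rate(1, 1), 0)
  expect_equal(precipitation_volume_rate(0, 3), 0)
  # hand evaluation: 0.113 * 2^2.26 * (0.1/2850) * 1
  expect_equal(precipitation_volume_rate(1, 3), 1.8991592e-5,
               tolerance = 1e-7)
  expect_error(precipitation_volume_rate(1, 0.5), "dissolution")
  expect_error(precipitation_volume_rate(-1, 3), ">= 0")
})

test_that("surface area shrinks with porosity to the 2/3 power", {
  expect_equal(surface_area_from_porosity(10, 0.4, 0.4), 10)
  expect_equal(surface_area_from_porosity(8, 0.05, 0.4), 2)  # (1/8)^(2/3)
  expect_lt(surface_area_from_porosity(10, 1e-12, 0.4), 1e-6)
  expect_error(surface_area_from_porosity(10, 0.5, 0.4), "reduces porosity")
  expect_error(surface_area_from_porosity(10, 0.4, 1.2), "phi0")
})

test_that("surface-area decline is maximal at onset and vanishes at pore closure", {
  base <- surface_area_rate(A0 = 2, phi0 = 0.4, V_t = 1, V_c = 0.6,
                            V_c0 = 0.6, Omega = 3)
  expect_lt(base, 0)
  nearly_full <- surface_area_rate(2, 0.4, 1, 0.6 + 0.4 * (1 - 1e-9),
                                   0.6, 3)
  expect_lt(abs(nearly_full), abs(base) * 1e-2)
  mid <- surface_area_rate(2, 0.4, 1, 0.8, 0.6, 3)
  expect_lt(abs(mid), abs(base))
  # A0^2 dependence: doubling A0 quadruples the magnitude
  expect_equal(surface_area_rate(4, 0.4, 1, 0.6, 0.6, 3), 4 * base)
  expect_error(surface_area_rate(2, 0.4, 1, 1.0, 0.6, 3), "V_t")
  expect_error(surface_area_rate(2, 0.4, 1, 0.5, 0.6, 3), "V_c0")
})

test_that("cementation flux reproduces the hand-computed oracle chain", {
  # A_sp = 5/(2850e-4); flux = (2/3)*0.283*(A_sp*0.6)^2/0.4*2850*0.1*
  #        0.113*2^2.26*0.05, evaluated independently = 403.0965
  flux <- cementation_energy_flux(Omega = 3, D = 1e-4, phi0 = 0.4, L = 0.05)
  expect_equal(as.numeric(flux), 403.0965, tolerance = 1e-6)
  expect_equal(as.numeric(cementation_energy_flux(1, 1e-4)), 0)
  expect_error(cementation_energy_flux(0.9, 1e-4), "dissolution")
})

test_that("flux ratios eliminate everything but the rate law", {
  r <- as.numeric(cementation_energy_flux(10, 1e-4)) /
    as.numeric(cementation_energy_flux(3, 1e-4))
  expect_equal(r, (9 / 2)^2.26, tolerance = 1e-10)
})

test_that("flux is monotone in saturation, grain size, length scale and porosity", {
  f <- function(...) as.numeric(cementation_energy_flux(...))
  omegas <- c(1.5, 2, 3, 5, 8, 10)
  expect_true(all(diff(vapply(omegas, f, numeric(1), D = 1e-4)) > 0))
  Ds <- c(4e-6, 2e-5, 1e-4, 5e-4)
  expect_true(all(diff(vapply(Ds, function(D) f(3, D), numeric(1))) < 0))
  # D^-2 scaling through A_sp^2
  expect_equal(f(3, 1e-4) / f(3, 2e-4), 4, tolerance = 1e-12)
  expect_equal(f(3, 1e-4, L = 0.1), 2 * f(3, 1e-4, L = 0.05))
  phis <- c(0.2, 0.4, 0.6)
  scaling <- (1 - phis)^2 / phis
  got <- vapply(phis, function(p) f(3, 1e-4, phi0 = p), numeric(1))
  expect_equal(got / got[1], scaling / scaling[1], tolerance = 1e-12)
})

test_that("volume- and area-based flux expressions agree on random states", {
  set.seed(11)
  kin <- aragonite_kinetics()
  for (i in 1:25) {
    phi0 <- runif(1, 0.2, 0.6)
    D <- 10^runif(1, -5.5, -3)
    V_t <- 10^runif(1, -3, 1)
    Omega <- runif(1, 1.2, 10)
    L <- runif(1, 0.01, 0.2)
    A_sp <- specific_surface_area(D, kin)
    A0 <- A_sp * (1 - phi0) * V_t * kin$rho_c
    V_c0 <- (1 - phi0) * V_t
    # sigma * dA/dt at onset, per unit volume, over window L = -|flux|
    dAdt <- surface_area_rate(A0, phi0, V_t, V_c0, V_c0, Omega, kin)
    lhs <- kin$sigma * dAdt / V_t * L
    rhs <- -as.numeric(cementation_energy_flux(Omega, D, phi0, L, kin))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})
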