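#' Carbonate mineral kinetic and interfacial parameters
#'
#' Bundles the mineral-specific constants that the cementation flux model
#' consumes: the specific interfacial free energy of the crystal--fluid
#' contact, the empirical precipitation rate law \eqn{k(\Omega-1)^n}, molar
#' mass, density, and a surface roughness factor that inflates the geometric
#' specific surface area.
#'
#' @param sigma Specific interfacial free energy of the mineral--fluid
#'   contact \[J m^-2\].
#' @param k Precipitation rate constant \[mol m^-2 yr^-1\]. The rate law is
#'   surface-normalized, so the canonical internal time unit of the package
#'   is the year.
#' @param n_exp Rate-law exponent on \eqn{(\Omega - 1)} \[-\], >= 1.
#' @param M_c Molar mass of the carbonate phase \[kg mol^-1\].
#' @param rho_c Density of the carbonate phase \[kg m^-3\].
#' @param r_f Surface roughness factor \[-\], >= 1; multiplies the smooth
#'   geometric surface-area-to-volume ratio.
#'
#' @return An object of class `mineral_kinetics` (a named list).
#' @seealso [aragonite_kinetics()] for the default aragonite parameter set.
#' @export
#' @examples
#' mineral_kinetics(sigma = 0.283, k = 0.113, n_exp = 2.26,
#'                  M_c = 0.1, rho_c = 2850, r_f = 5)
mineral_kinetics <- function(sigma, k, n_exp, M_c, rho_c, r_f) {
  vals <- c(sigma = sigma, k = k, n_exp = n_exp, M_c = M_c,
            rho_c = rho_c, r_f = r_f)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all mineral kinetic parameters must be finite and strictly positive",
         call. = FALSE)
  }
  if (n_exp < 1) stop("rate-law exponent n_exp must be >= 1", call. = FALSE)
  if (r_f < 1) stop("roughness factor r_f must be >= 1", call. = FALSE)
  structure(list(sigma = sigma, k = k, n_exp = n_exp, M_c = M_c,
                 rho_c = rho_c, r_f = r_f),
            class = "mineral_kinetics")
}

#' Default aragonite parameter set
#'
#' Standard constants for marine aragonite precipitation: interfacial free
#' energy 0.283 J m^-2, rate constant 0.113 mol m^-2 yr^-1 with exponent
#' 2.26, molar mass 0.1 kg mol^-1, density 2850 kg m^-3, and a surface
#' roughness factor of five appropriate for both shallow- and deep-water
#' carbonate sediments.
#'
#' @return A [mineral_kinetics()] object.
#' @export
#' @examples
#' aragonite_kinetics()$sigma  # 0.283
aragonite_kinetics <- function() {
  mineral_kinetics(sigma = 0.283, k = 0.113, n_exp = 2.26,
                   M_c = 0.1, rho_c = 2850, r_f = 5)
}

#' @export
print.mineral_kinetics <- function(x, ...) {
  cat("Mineral kinetics:\n")
  cat(sprintf("  sigma = %g J m^-2   k = %g mol m^-2 yr^-1   n = %g\n",
              x$sigma, x$k, x$n_exp))
  cat(sprintf("  M_c = %g kg mol^-1  rho_c = %g kg m^-3      r_f = %g\n",
              x$M_c, x$rho_c, x$r_f))
  invisible(x)
}

#' Fluid and physical constants
#'
#' Seawater density, kinematic viscosity, gravitational acceleration, the
#' von Karman constant used by the log-law velocity profile, and the
#' seconds-per-year conversion applied at the flux boundary between the
#' hydraulic submodels (which work in seconds) and the kinetic rate laws
#' (which work in years).
#'
#' @param rho_w Water density \[kg m^-3\].
#' @param nu Kinematic viscosity \[m^2 s^-1\].
#' @param g Gravitational acceleration \[m s^-2\].
#' @param kappa von Karman constant \[-\]; must lie in (0.3, 0.5).
#' @param seconds_per_year Unit conversion \[s yr^-1\].
#'
#' @return An object of class `fluid_constants` (a named list).
#' @export
#' @examples
#' fluid_constants()            # seawater defaults
#' fluid_constants(rho_w = 1000)  # fresh water
fluid_constants <- function(rho_w = 1025, nu = 1.0e-6, g = 9.81,
                            kappa = 0.41, seconds_per_year = 3.156e7) {
  vals <- c(rho_w = rho_w, nu = nu, g = g, kappa = kappa,
            seconds_per_year = seconds_per_year)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all fluid constants must be finite and strictly positive",
         call. = FALSE)
  }
  if (kappa <= 0.3 || kappa >= 0.5) {
    stop("von Karman constant kappa must lie in (0.3, 0.5)", call. = FALSE)
  }
  structure(list(rho_w = rho_w, nu = nu, g = g, kappa = kappa,
                 seconds_per_year = seconds_per_year),
            class = "fluid_constants")
}

#' @export
print.fluid_constants <- function(x, ...) {
  cat("Fluid constants:\n")
  cat(sprintf("  rho_w = %g kg m^-3  nu = %g m^2 s^-1  g = %g m s^-2\n",
              x$rho_w, x$nu, x$g))
  cat(sprintf("  kappa = %g          s/yr = %g\n", x$kappa, x$seconds_per_year))
  invisible(x)
}

#' Construct an energy flux
#'
#' An energy flux is an area-normalized power, \[J m^-2 yr^-1\], tagged with
#' the process that produced it. Chemical fluxes are stored as magnitudes;
#' their negative sign is applied only in the energy balance, where
#' cementation removes surface area while the two physical fluxes create it.
#'
#' @param value Flux magnitude \[J m^-2 yr^-1\]; must be finite and >= 0.
#' @param source One of `"chemical"`, `"transport"`, `"bioturbation"`.
#'
#' @return A numeric of class `energy_flux` carrying a `source` attribute.
#' @export
#' @examples
#' energy_flux(26.9, "bioturbation")
energy_flux <- function(value, source = c("chemical", "transport",
                                          "bioturbation")) {
  source <- match.arg(source)
  if (any(!is.finite(value))) {
    stop("energy flux must be finite", call. = FALSE)
  }
  if (any(value < 0)) {
    stop("energy fluxes are stored as magnitudes; got a negative value",
         call. = FALSE)
  }
  structure(value, source = source, class = "energy_flux")
}

#' @export
print.energy_flux <- function(x, ...) {
  cat(sprintf("<energy flux, %s>\n", attr(x, "source")))
  print(as.numeric(x))
  invisible(x)
}

#' Source process of an energy flux
#' @param x An `energy_flux`.
#' @return The source label.
#' @export
flux_source <- function(x) attr(x, "source")

#' Convert a flux between per-second and per-year bases
#'
#' The hydraulic submodels compute power densities in \[J m^-2 s^-1\]; the
#' kinetic rate laws use years. These helpers move values across that
#' boundary using the `seconds_per_year` member of the fluid constants, and
#' round-trip to within floating-point precision.
#'
#' @param flux_per_second Flux in \[J m^-2 s^-1\].
#' @param flux_per_year Flux in \[J m^-2 yr^-1\].
#' @param fluid A [fluid_constants()] object supplying the conversion.
#' @return The converted numeric flux.
#' @export
#' @examples
#' to_per_year(2e-8)                 # ~0.631 J m^-2 yr^-1
#' to_per_second(to_per_year(1))     # 1
to_per_year <- function(flux_per_second, fluid = fluid_constants()) {
  if (any(!is.finite(flux_per_second))) {
    stop("flux must be finite", call. = FALSE)
  }
  flux_per_second * fluid$seconds_per_year
}

#' @rdname to_per_year
#' @export
to_per_second <- function(flux_per_year, fluid = fluid_constants()) {
  if (any(!is.finite(flux_per_year))) {
    stop("flux must be finite", call. = FALSE)
  }
  flux_per_year / fluid$seconds_per_year
}
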