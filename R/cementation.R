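#' Named grain-size classes
#'
#' Representative grain diameters \[m\] used for the chemical flux bands:
#' mud 4 um, silt 20 um, fine sand 125 um, sand 250 um, coarse sand 500 um.
#'
#' @format Named numeric vector of diameters in metres.
#' @export
grain_size_classes <- c(mud = 4e-6, silt = 2e-5, fine_sand = 1.25e-4,
                        sand = 2.5e-4, coarse_sand = 5e-4)

#' Resolve a grain diameter from a number or class name
#' @param D A positive diameter \[m\] or one of `names(grain_size_classes)`.
#' @return Diameter in metres.
#' @export
#' @examples
#' resolve_grain_size("fine_sand")  # 1.25e-4
resolve_grain_size <- function(D) {
  if (is.character(D)) {
    if (!all(D %in% names(grain_size_classes))) {
      stop("unknown grain-size class: ",
           paste(setdiff(D, names(grain_size_classes)), collapse = ", "),
           call. = FALSE)
    }
    return(unname(grain_size_classes[D]))
  }
  if (any(!is.finite(D)) || any(D <= 0)) {
    stop("grain diameter D must be finite and > 0", call. = FALSE)
  }
  D
}

#' Specific surface area of granular sediment
#'
#' Geometric model in which the reactive surface area per unit mass scales
#' inversely with grain diameter, inflated by the mineral's surface
#' roughness factor: \eqn{A_{sp} = r_f / (\rho_c D)}. A `sphere_factor`
#' switch exposes the alternative reading in which an ideal sphere's
#' surface-to-volume ratio (6/D) enters the bracket; the default of 1
#' follows the model as usually printed.
#'
#' @param D Grain diameter \[m\] or a named grain-size class.
#' @param kin A [mineral_kinetics()] object.
#' @param sphere_factor Geometric prefactor inside the bracket (default 1).
#' @return Specific surface area \[m^2 kg^-1\].
#' @export
#' @examples
#' specific_surface_area(1e-4)  # 17.54 m^2/kg for aragonite defaults
specific_surface_area <- function(D, kin = aragonite_kinetics(),
                                  sphere_factor = 1) {
  D <- resolve_grain_size(D)
  sphere_factor * kin$r_f / (kin$rho_c * D)
}

#' Carbonate precipitation volume rate
#'
#' Volumetric growth rate of carbonate cement on a reactive surface,
#' \eqn{dV_c/dt = k(\Omega-1)^n (M_c/\rho_c) A}. Only the precipitation
#' branch (\eqn{\Omega \ge 1}) is modeled; dissolution is a domain error.
#'
#' @param A Reactive surface area \[m^2\], >= 0.
#' @param Omega Saturation state \[-\], >= 1.
#' @param kin A [mineral_kinetics()] object.
#' @return Volume rate \[m^3 yr^-1\].
#' @export
#' @examples
#' precipitation_volume_rate(1, 3)  # ~1.9e-5 m^3/yr
precipitation_volume_rate <- function(A, Omega, kin = aragonite_kinetics()) {
  if (any(A < 0)) stop("surface area A must be >= 0", call. = FALSE)
  if (any(Omega < 1)) {
    stop("Omega < 1: dissolution is not modeled (precipitation-only rate law)",
         call. = FALSE)
  }
  kin$k * (Omega - 1)^kin$n_exp * (kin$M_c / kin$rho_c) * A
}

#' Surface area as a function of porosity
#'
#' During cementation pore space closes and the crystal--fluid surface area
#' shrinks as \eqn{A = A_0 (\phi/\phi_0)^{2/3}}. Valid only for
#' \eqn{0 < \phi \le \phi_0}: cementation never increases porosity.
#'
#' @param A0 Initial surface area \[m^2\].
#' @param phi Current porosity \[-\].
#' @param phi0 Initial porosity \[-\].
#' @return Surface area \[m^2\].
#' @export
surface_area_from_porosity <- function(A0, phi, phi0) {
  if (any(phi0 <= 0) || any(phi0 >= 1)) {
    stop("initial porosity phi0 must lie in (0, 1)", call. = FALSE)
  }
  if (any(phi <= 0) || any(phi > phi0)) {
    stop("porosity phi must lie in (0, phi0]: cementation only reduces porosity",
         call. = FALSE)
  }
  A0 * (phi / phi0)^(2 / 3)
}

#' Rate of surface-area change during cementation
#'
#' Chains the porosity--surface-area relation, the porosity--carbonate-volume
#' identity, and the precipitation rate law into
#' \deqn{dA/dt = -\frac{2}{3}\frac{A_0^2}{\phi_0 V_t}
#'       \left[\frac{V_t - V_c}{V_t - V_{c0}}\right]^{1/3}
#'       \frac{M_c}{\rho_c} k(\Omega-1)^n,}
#' which is always <= 0: precipitation destroys surface area. The bracketed
#' attenuation equals one at the onset of cementation (\eqn{V_c = V_{c0}}),
#' where the magnitude is maximal, and tends to zero as the carbonate volume
#' approaches the total volume.
#'
#' @param A0 Initial surface area \[m^2\].
#' @param phi0 Initial porosity \[-\].
#' @param V_t Total (sediment + pore) volume \[m^3\].
#' @param V_c Current carbonate volume \[m^3\], in \[V_c0, V_t).
#' @param V_c0 Initial carbonate volume \[m^3\].
#' @param Omega Saturation state, >= 1.
#' @param kin A [mineral_kinetics()] object.
#' @return dA/dt \[m^2 yr^-1\] (non-positive).
#' @export
surface_area_rate <- function(A0, phi0, V_t, V_c, V_c0, Omega,
                              kin = aragonite_kinetics()) {
  if (any(V_c0 > V_c)) stop("V_c must be >= V_c0", call. = FALSE)
  if (any(V_c >= V_t)) {
    stop("V_c must be < V_t: pore space cannot be overfilled", call. = FALSE)
  }
  if (any(Omega < 1)) {
    stop("Omega < 1: dissolution is not modeled", call. = FALSE)
  }
  atten <- ((V_t - V_c) / (V_t - V_c0))^(1 / 3)
  -(2 / 3) * A0^2 / (phi0 * V_t) * atten *
    (kin$M_c / kin$rho_c) * kin$k * (Omega - 1)^kin$n_exp
}

#' Chemical energy flux of carbonate cementation
#'
#' Maximum rate at which interfacial free energy is lost to cementation,
#' per unit seafloor area, evaluated at the onset of cementation where the
#' surface-area decline is fastest:
#' \deqn{|dE_{chem}/dt| = \frac{2}{3}\sigma
#'   \frac{(A_{sp}(1-\phi_0))^2}{\phi_0}\rho_c M_c k(\Omega-1)^n L.}
#' The observation window \eqn{L} converts the volume-normalized rate to an
#' area-normalized one; its default of 0.05 m is the median depth of active
#' bioturbation, so the chemical and biological fluxes refer to the same
#' slab of sediment.
#'
#' @param Omega Saturation state \[-\], >= 1. `Omega = 1` gives zero flux.
#' @param D Grain diameter \[m\] or named grain-size class.
#' @param phi0 Initial porosity \[-\] in (0, 1).
#' @param L Vertical observation length \[m\].
#' @param kin A [mineral_kinetics()] object.
#' @param sphere_factor Passed to [specific_surface_area()].
#' @return An [energy_flux()] with source `"chemical"` \[J m^-2 yr^-1\],
#'   stored as a magnitude; the balance applies its negative sign.
#' @export
#' @examples
#' cementation_energy_flux(Omega = 3, D = 1e-4)  # ~403 J m^-2 yr^-1
cementation_energy_flux <- function(Omega, D, phi0 = 0.4, L = 0.05,
                                    kin = aragonite_kinetics(),
                                    sphere_factor = 1) {
  if (any(Omega < 1)) {
    stop("Omega < 1: dissolution is not modeled", call. = FALSE)
  }
  if (any(phi0 <= 0) || any(phi0 >= 1)) {
    stop("initial porosity phi0 must lie in (0, 1)", call. = FALSE)
  }
  if (any(L <= 0)) stop("observation length L must be > 0", call. = FALSE)
  A_sp <- specific_surface_area(D, kin, sphere_factor)
  mag <- (2 / 3) * kin$sigma * (A_sp * (1 - phi0))^2 / phi0 *
    kin$rho_c * kin$M_c * kin$k * (Omega - 1)^kin$n_exp * L
  energy_flux(mag, "chemical")
}
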