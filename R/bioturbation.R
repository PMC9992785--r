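#' Gravitational excavation energy flux
#'
#' Lower-bound end member for bioturbation: upward-conveyor organisms lift
#' excavated sediment from depth to the sediment--water interface, so the
#' energy flux must at least account for the change in gravitational
#' potential energy of the particles,
#' \deqn{dE_{gr}/dt = \tfrac{1}{2}(1-\phi)(\rho_s-\rho_w)\,R\,g\,d.}
#' Linear in the volumetric reworking rate \eqn{R} and in the burrow depth
#' \eqn{d}.
#'
#' @param R Volumetric reworking rate \[m^3 m^-2 yr^-1\], >= 0.
#' @param d Burrow depth \[m\], > 0.
#' @param phi Sediment porosity \[-\].
#' @param rho_s Sediment grain density \[kg m^-3\]; must exceed the water
#'   density (non-sinking sediment is rejected).
#' @param fluid A [fluid_constants()] object (supplies g and rho_w).
#' @return An [energy_flux()] with source `"bioturbation"`
#'   \[J m^-2 yr^-1\]. Vectorized over `R` and `d`.
#' @export
#' @examples
#' excavation_flux(R = 0.1, d = 0.05)  # ~26.9 J m^-2 yr^-1
excavation_flux <- function(R, d, phi = 0.4, rho_s = 2850,
                            fluid = fluid_constants()) {
  if (any(R < 0)) stop("reworking rate R must be >= 0", call. = FALSE)
  if (any(d <= 0)) stop("burrow depth d must be > 0", call. = FALSE)
  if (any(rho_s <= fluid$rho_w)) {
    stop("rho_s <= rho_w: non-sinking sediment", call. = FALSE)
  }
  energy_flux(0.5 * (1 - phi) * (rho_s - fluid$rho_w) * R * fluid$g * d,
              "bioturbation")
}

#' Crack-propagation energy flux
#'
#' Upper-bound end member: burrowing through cohesive substrate modeled as
#' propagating a fracture tip, which must pay the fracture toughness of the
#' sediment over the crack area,
#' \deqn{dE_{cr}/dt = 2 G_c R / (\pi b),}
#' where \eqn{b} is the burrow radius (half the burrow width). Linear in
#' \eqn{R}, inversely proportional to \eqn{b}.
#'
#' @param R Volumetric reworking rate \[m^3 m^-2 yr^-1\], >= 0.
#' @param b Burrow radius \[m\], > 0.
#' @param G_c Fracture toughness of the substrate \[J m^-2\]; the default
#'   of 1 is an order-of-magnitude value for cohesive marine muds.
#' @return An [energy_flux()] with source `"bioturbation"`
#'   \[J m^-2 yr^-1\]. Vectorized.
#' @export
#' @examples
#' crack_flux(R = 0.1, b = 0.005)  # ~12.7 J m^-2 yr^-1
crack_flux <- function(R, b, G_c = 1) {
  if (any(R < 0)) stop("reworking rate R must be >= 0", call. = FALSE)
  if (any(b <= 0)) stop("burrow radius b must be > 0", call. = FALSE)
  if (any(G_c <= 0)) stop("fracture toughness G_c must be > 0", call. = FALSE)
  energy_flux(2 * G_c * R / (pi * b), "bioturbation")
}

#' Work of excavating one cylindrical burrow
#'
#' Energy required to lift the contents of a cylindrical burrow of radius
#' `b` extending to depth `d` up to the sediment--water interface. The
#' closed form is \eqn{E_{gr} = \tfrac12 (1-\phi)(\rho_s-\rho_w)\pi b^2 g d^2}
#' (equivalent to raising the full buoyant mass from half the burrow
#' depth). `method = "riemann"` instead sums the work of lifting
#' `n_segments` discrete slabs; with left endpoints it converges to the
#' closed form from below at order 1/n, and with the midpoint rule it is
#' exact for any n because the integrand is linear in depth. The discrete
#' sum serves as an independent check on the closed form.
#'
#' @param b Burrow radius \[m\].
#' @param d Burrow depth \[m\], >= 0.
#' @param phi Sediment porosity \[-\].
#' @param rho_s Sediment grain density \[kg m^-3\].
#' @param fluid A [fluid_constants()] object.
#' @param method `"closed"` (default) or `"riemann"`.
#' @param n_segments Number of slabs for the Riemann sum, >= 1.
#' @param rule `"left"` or `"midpoint"` endpoints for the slabs.
#' @return Work per burrow \[J\].
#' @export
#' @examples
#' excavation_work(b = 0.005, d = 0.1)
#' excavation_work(b = 0.005, d = 0.1, method = "riemann", n_segments = 1e5)
excavation_work <- function(b, d, phi = 0.4, rho_s = 2850,
                            fluid = fluid_constants(),
                            method = c("closed", "riemann"),
                            n_segments = 1000L,
                            rule = c("left", "midpoint")) {
  method <- match.arg(method)
  rule <- match.arg(rule)
  if (b <= 0) stop("burrow radius b must be > 0", call. = FALSE)
  if (d < 0) stop("burrow depth d must be >= 0", call. = FALSE)
  coef <- (1 - phi) * (rho_s - fluid$rho_w) * pi * b^2 * fluid$g
  if (method == "closed") return(0.5 * coef * d^2)
  n <- as.integer(n_segments)
  if (n < 1L) stop("n_segments must be >= 1", call. = FALSE)
  dz <- d / n
  z <- if (rule == "left") (seq_len(n) - 1) * dz else (seq_len(n) - 0.5) * dz
  coef * dz * sum(z)
}
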