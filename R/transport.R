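#' Terminal settling velocity of a grain
#'
#' Ferguson--Church closed form, which interpolates between the Stokes
#' (viscous) limit for fine grains and the turbulent-drag limit for coarse
#' ones:
#' \deqn{w_s = \frac{R' g D^2}{C_1 \nu + \sqrt{0.75\, C_2 R' g D^3}},}
#' with submerged specific gravity \eqn{R' = (\rho_s - \rho_w)/\rho_w}.
#' Defaults \eqn{C_1 = 18}, \eqn{C_2 = 1} (natural grains).
#'
#' @param D Grain diameter \[m\].
#' @param rho_s Grain density \[kg m^-3\].
#' @param fluid A [fluid_constants()] object.
#' @param C1,C2 Ferguson--Church drag coefficients.
#' @return Settling velocity \[m s^-1\].
#' @export
settling_velocity <- function(D, rho_s = 2850, fluid = fluid_constants(),
                              C1 = 18, C2 = 1.0) {
  if (any(!is.finite(D)) || any(D <= 0)) {
    stop("grain diameter D must be finite and > 0", call. = FALSE)
  }
  Rp <- (rho_s - fluid$rho_w) / fluid$rho_w
  if (Rp < 0) stop("rho_s < rho_w: buoyant grains do not settle", call. = FALSE)
  Rp * fluid$g * D^2 / (C1 * fluid$nu + sqrt(0.75 * C2 * Rp * fluid$g * D^3))
}

#' Critical Shields number (threshold of motion)
#'
#' Explicit Brownlie fit of the Shields curve (default),
#' \eqn{\tau^*_c = 0.22\,Re_p^{-0.6} + 0.06 \cdot 10^{-7.7 Re_p^{-0.6}}}
#' with particle Reynolds number \eqn{Re_p = \sqrt{R' g D}\, D / \nu},
#' or a constant value via `method = "constant"`.
#'
#' @param D Grain diameter \[m\].
#' @param rho_s Grain density \[kg m^-3\].
#' @param fluid A [fluid_constants()] object.
#' @param method `"brownlie"` or `"constant"`.
#' @param const Constant critical Shields number when `method = "constant"`.
#' @return Critical Shields number \[-\].
#' @export
critical_shields <- function(D, rho_s = 2850, fluid = fluid_constants(),
                             method = c("brownlie", "constant"),
                             const = 0.03) {
  method <- match.arg(method)
  if (method == "constant") return(rep_len(const, length(D)))
  Rp <- (rho_s - fluid$rho_w) / fluid$rho_w
  Re_p <- sqrt(Rp * fluid$g * D) * D / fluid$nu
  0.22 * Re_p^-0.6 + 0.06 * 10^(-7.7 * Re_p^-0.6)
}

#' Shields number and its critical value
#'
#' \eqn{\tau^* = \rho_w u_*^2 / ((\rho_s - \rho_w) g D)} together with the
#' threshold of motion from [critical_shields()]. Sediments with
#' \eqn{\tau^* < \tau^*_c} are immobile on the bed surface.
#'
#' @param D Grain diameter \[m\].
#' @param u_star Shear velocity \[m s^-1\], >= 0.
#' @param rho_s Grain density \[kg m^-3\].
#' @param fluid A [fluid_constants()] object.
#' @param ... Passed to [critical_shields()].
#' @return List with `tau_star` and `tau_star_c`.
#' @export
shields_numbers <- function(D, u_star, rho_s = 2850,
                            fluid = fluid_constants(), ...) {
  if (any(D <= 0)) stop("grain diameter D must be > 0", call. = FALSE)
  if (any(u_star < 0)) stop("shear velocity must be >= 0", call. = FALSE)
  tau_star <- fluid$rho_w * u_star^2 / ((rho_s - fluid$rho_w) * fluid$g * D)
  list(tau_star = tau_star,
       tau_star_c = critical_shields(D, rho_s, fluid, ...))
}

#' Bedload layer height and velocity
#'
#' Empirical transport-stage scalings for the near-bed layer in which
#' grains roll and saltate:
#' \eqn{H_b = 1.44\,D\,(\tau^*/\tau^*_c)^{0.5}} (capped at the flow depth)
#' and \eqn{U_b = 1.56\sqrt{R' g D}\,(\tau^*/\tau^*_c)^{0.56}}.
#' Callers must short-circuit to zero flux below threshold; this function
#' rejects sub-threshold input.
#'
#' @param D Grain diameter \[m\].
#' @param tau_star Shields number \[-\].
#' @param tau_star_c Critical Shields number \[-\].
#' @param rho_s Grain density \[kg m^-3\].
#' @param fluid A [fluid_constants()] object.
#' @param H Flow depth \[m\] used to cap `H_b` (default uncapped).
#' @return List with `H_b` \[m\] and `U_b` \[m s^-1\].
#' @export
bedload_layer <- function(D, tau_star, tau_star_c, rho_s = 2850,
                          fluid = fluid_constants(), H = Inf) {
  if (any(tau_star < tau_star_c)) {
    stop("tau_star < tau_star_c: below the threshold of motion ",
         "(callers must short-circuit to zero flux)", call. = FALSE)
  }
  stage <- tau_star / tau_star_c
  Rp <- (rho_s - fluid$rho_w) / fluid$rho_w
  list(H_b = pmin(1.44 * D * stage^0.5, H),
       U_b = 1.56 * sqrt(Rp * fluid$g * D) * stage^0.56)
}

#' Depth-averaged log-law velocity
#'
#' Average of \eqn{u(z) = (u_*/\kappa)\ln(z/z_0)} over \eqn{[z_0, H]} with
#' roughness length \eqn{z_0 = D/30}.
#'
#' @inheritParams shields_numbers
#' @param H Flow depth \[m\].
#' @return Depth-averaged velocity \[m s^-1\].
#' @export
depth_averaged_velocity <- function(u_star, D, H, fluid = fluid_constants()) {
  z0 <- D / 30
  if (any(H <= z0)) stop("flow depth H must exceed z0 = D/30", call. = FALSE)
  (u_star / fluid$kappa) * (log(H / z0) - 1 + z0 / H)
}

#' Suspension profile integral
#'
#' Dimensionless overlap of the vertical velocity and suspended-sediment
#' concentration profiles,
#' \deqn{\chi = \frac{1}{U H}\int_{H_b}^{H} u(z)\,\hat c(z)\,dz,}
#' with the log-law \eqn{u(z) = (u_*/\kappa)\ln(z/z_0)}, \eqn{z_0 = D/30},
#' and the Rouse profile
#' \eqn{\hat c(z) = [((H-z)/z) \cdot (H_b/(H-H_b))]^P} normalized to 1 at
#' the top of the bedload layer, with Rouse number
#' \eqn{P = w_s/(\kappa u_*)}. Evaluated by adaptive quadrature.
#' \eqn{\chi \to 0} as \eqn{P \to \infty} (all sediment collapses onto the
#' bed) and \eqn{\chi \approx 1} for \eqn{P = 0} with \eqn{H_b \ll H}
#' (well-mixed suspension).
#'
#' @param D Grain diameter \[m\] (sets the roughness length).
#' @param u_star Shear velocity \[m s^-1\], > 0.
#' @param H Flow depth \[m\].
#' @param H_b Bedload layer height \[m\], < H.
#' @param w_s Settling velocity \[m s^-1\].
#' @param fluid A [fluid_constants()] object.
#' @param rel_tol Relative tolerance of the quadrature.
#' @return The integral \eqn{\chi} \[-\].
#' @export
suspension_integral_chi <- function(D, u_star, H, H_b, w_s,
                                    fluid = fluid_constants(),
                                    rel_tol = 1e-8) {
  if (any(c(D, u_star, H, H_b) <= 0)) {
    stop("D, u_star, H and H_b must be > 0", call. = FALSE)
  }
  if (H_b >= H) stop("H_b must be < H", call. = FALSE)
  if (w_s < 0) stop("settling velocity must be >= 0", call. = FALSE)
  z0 <- D / 30
  P <- w_s / (fluid$kappa * u_star)
  U <- depth_averaged_velocity(u_star, D, H, fluid)
  ref <- H_b / (H - H_b)
  integrand <- function(z) {
    u <- (u_star / fluid$kappa) * log(z / z0)
    chat <- (((H - z) / z) * ref)^P
    chat[!is.finite(chat)] <- 0   # z -> H underflow/0^P edge
    u * chat
  }
  val <- tryCatch(
    stats::integrate(integrand, lower = H_b, upper = H,
                     rel.tol = rel_tol, subdivisions = 500L)$value,
    error = function(e) {
      stop(sprintf(
        "suspension integral failed to converge (D=%g, u_star=%g, H=%g, H_b=%g, w_s=%g): %s",
        D, u_star, H, H_b, w_s, conditionMessage(e)), call. = FALSE)
    })
  val / (U * H)
}

#' Particle Stokes number of a settling grain
#'
#' \eqn{St = (\rho_s / 9\rho_w)\, w_s D / \nu}; governs whether the kinetic
#' energy of an impacting grain survives the near-bed fluid film.
#'
#' @param w_s Settling velocity \[m s^-1\].
#' @param D Grain diameter \[m\].
#' @param rho_s Grain density \[kg m^-3\].
#' @param fluid A [fluid_constants()] object.
#' @return Stokes number \[-\].
#' @export
stokes_number <- function(w_s, D, rho_s = 2850, fluid = fluid_constants()) {
  (rho_s / (9 * fluid$rho_w)) * w_s * D / fluid$nu
}

#' Impact velocity with viscous damping
#'
#' Grain impacts on the bed are fully damped by the near-bed fluid below a
#' lower Stokes threshold, undamped above an upper one, with a linear ramp
#' between: \eqn{w_i = 0} for \eqn{St \le St_{low}}, \eqn{w_i = w_s} for
#' \eqn{St \ge St_{high}}. Fine muds therefore transfer no impact energy --
#' the cementation-favorable zone at the fine-grained edge of regime maps.
#'
#' @inheritParams stokes_number
#' @param St_low,St_high Damping ramp thresholds (defaults 30 and 75).
#' @return Impact velocity normal to the bed \[m s^-1\], always <= `w_s`.
#' @export
impact_velocity <- function(w_s, D, rho_s = 2850, fluid = fluid_constants(),
                            St_low = 30, St_high = 75) {
  if (St_high <= St_low) stop("St_high must exceed St_low", call. = FALSE)
  St <- stokes_number(w_s, D, rho_s, fluid)
  frac <- pmin(pmax((St - St_low) / (St_high - St_low), 0), 1)
  frac * w_s
}

#' Transport capacity sediment supply
#'
#' Declared Engelund--Hansen-type capacity relation,
#' \eqn{q = C\, u_*^5 / (R'^2 g^2 D)} \[m^2 s^-1\] (volumetric supply per
#' unit flow width), equivalent to a dimensionless total load
#' \eqn{q^* = C\,(\tau^*)^{2.5}}.
#'
#' @inheritParams shields_numbers
#' @param coef Capacity coefficient (default 0.05).
#' @return Volumetric sediment supply per unit width \[m^2 s^-1\].
#' @export
capacity_supply <- function(u_star, D, rho_s = 2850,
                            fluid = fluid_constants(), coef = 0.05) {
  Rp <- (rho_s - fluid$rho_w) / fluid$rho_w
  coef * u_star^5 / (Rp^2 * fluid$g^2 * D)
}

#' Derived transport quantities for one flow state
#'
#' Computes every submodel the kinetic energy flux consumes -- settling
#' velocity, Shields numbers, Stokes number, damped impact velocity, and
#' (above threshold) the bedload layer, depth-averaged velocity, and
#' suspension integral. Pure function of its inputs: repeated calls are
#' bitwise identical.
#'
#' @param u_star Shear velocity \[m s^-1\].
#' @param D Grain diameter \[m\] or named grain-size class.
#' @param H Flow depth \[m\] (default 1).
#' @param rho_s Density of the (carbonate) grains \[kg m^-3\].
#' @param fluid A [fluid_constants()] object.
#' @param St_low,St_high Viscous damping thresholds (see
#'   [impact_velocity()]).
#' @param shields_method,shields_const Critical-Shields options (see
#'   [critical_shields()]).
#' @param chi_rel_tol Quadrature tolerance for [suspension_integral_chi()].
#' @return A list of class `transport_derived` with members `w_s`, `w_i`,
#'   `St`, `tau_star`, `tau_star_c`, `mobile`, and (when mobile) `H_b`,
#'   `U_b`, `U`, `chi` (zero otherwise).
#' @export
transport_derived <- function(u_star, D, H = 1, rho_s = 2850,
                              fluid = fluid_constants(),
                              St_low = 30, St_high = 75,
                              shields_method = "brownlie",
                              shields_const = 0.03,
                              chi_rel_tol = 1e-8) {
  D <- resolve_grain_size(D)
  stopifnot(length(u_star) == 1L, length(D) == 1L)
  if (H <= 0) stop("flow depth H must be > 0", call. = FALSE)
  w_s <- settling_velocity(D, rho_s, fluid)
  sh <- shields_numbers(D, u_star, rho_s, fluid,
                        method = shields_method, const = shields_const)
  St <- stokes_number(w_s, D, rho_s, fluid)
  w_i <- impact_velocity(w_s, D, rho_s, fluid, St_low, St_high)
  mobile <- sh$tau_star >= sh$tau_star_c
  out <- list(w_s = w_s, w_i = w_i, St = St,
              tau_star = sh$tau_star, tau_star_c = sh$tau_star_c,
              mobile = mobile, H_b = 0, U_b = 0, U = 0, chi = 0)
  if (mobile) {
    bl <- bedload_layer(D, sh$tau_star, sh$tau_star_c, rho_s, fluid, H)
    out$H_b <- bl$H_b
    out$U_b <- bl$U_b
    out$U <- depth_averaged_velocity(u_star, D, H, fluid)
    if (bl$H_b < H) {
      out$chi <- suspension_integral_chi(D, u_star, H, bl$H_b, w_s,
                                         fluid, chi_rel_tol)
    }
  }
  structure(out, class = "transport_derived")
}

#' Kinetic energy flux from sediment transport
#'
#' Rate at which saltating and suspended grains deliver kinetic energy to
#' the bed, per unit seafloor area:
#' \deqn{\frac{dE_{sed}}{dt} = \frac{1}{2}
#'   \frac{A_1 \rho_c q\, w_i^3}{U H \chi + U_b H_b},}
#' converted to \[J m^-2 yr^-1\]. The flux is exactly zero below the
#' threshold of motion, when viscous damping suppresses impacts
#' (\eqn{w_i = 0}), or when the sediment supply vanishes. With
#' `q = "capacity"` the supply follows the declared capacity relation
#' [capacity_supply()], so the flux goes continuously to zero at the
#' threshold through \eqn{q \to 0}; a user-fixed `q` instead jumps there
#' (documented behavior).
#'
#' @param u_star Shear velocity \[m s^-1\].
#' @param D Grain diameter \[m\] or named grain-size class.
#' @param H Flow depth \[m\].
#' @param q `"capacity"` or a volumetric sediment supply per unit width
#'   \[m^2 s^-1\].
#' @param rho_s Density of the impacting carbonate grains \[kg m^-3\]; also
#'   used by the hydraulic submodels.
#' @param A1 Dimensionless energy-transfer efficiency (default 0.3).
#' @param duty_cycle Fraction of time the flow is transporting (default 1:
#'   fluxes are while-transporting rates; storm intermittency is not
#'   modeled).
#' @param capacity_coef Coefficient of the capacity relation.
#' @param fluid A [fluid_constants()] object.
#' @param derived Optional precomputed [transport_derived()] object.
#' @param ... Passed to [transport_derived()].
#' @return An [energy_flux()] with source `"transport"` \[J m^-2 yr^-1\].
#' @export
#' @examples
#' sediment_energy_flux(u_star = 0.1, D = 2e-3)
#' sediment_energy_flux(u_star = 0.001, D = 2e-3)  # below threshold: 0
sediment_energy_flux <- function(u_star, D, H = 1, q = "capacity",
                                 rho_s = 2850, A1 = 0.3, duty_cycle = 1,
                                 capacity_coef = 0.05,
                                 fluid = fluid_constants(),
                                 derived = NULL, ...) {
  D <- resolve_grain_size(D)
  if (A1 <= 0 || A1 > 1) stop("A1 must lie in (0, 1]", call. = FALSE)
  if (is.null(derived)) {
    derived <- transport_derived(u_star, D, H, rho_s, fluid, ...)
  }
  zero <- energy_flux(0, "transport")
  if (!derived$mobile || derived$w_i <= 0) return(zero)
  if (identical(q, "capacity")) {
    q <- capacity_supply(u_star, D, rho_s, fluid, capacity_coef)
  }
  if (q < 0) stop("sediment supply q must be >= 0", call. = FALSE)
  if (q == 0) return(zero)
  denom <- derived$U * H * derived$chi + derived$U_b * derived$H_b
  if (denom <= 0) {
    warning("no transport volume (U*H*chi + U_b*H_b = 0); returning zero flux")
    return(zero)
  }
  flux_per_s <- 0.5 * A1 * rho_s * q * derived$w_i^3 / denom
  energy_flux(to_per_year(flux_per_s, fluid) * duty_cycle, "transport")
}
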