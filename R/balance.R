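#' Seafloor interfacial energy balance
#'
#' Signed balance of the three competing fluxes,
#' \deqn{dG_{int}/dt = dE_{sed}/dt + dE_{bio}/dt - dE_{chem}/dt.}
#' The chemical flux enters negatively: cementation destroys crystal--fluid
#' surface area while grain impacts and burrowing create it. A positive
#' balance means kinetic energy dislodges nascent cements and cohesive
#' substrates cannot form; a negative balance means cementation wins and
#' grains aggregate into cohesive, early-lithified substrates.
#'
#' @param E_sed,E_bio,E_chem Flux magnitudes \[J m^-2 yr^-1\], >= 0.
#' @return A list of class `energy_budget` with the three fluxes and the
#'   signed rate `dGint_dt`.
#' @export
#' @examples
#' energy_balance(0, 26.9, 403.1)   # cementation-favored
energy_balance <- function(E_sed, E_bio, E_chem) {
  vals <- c(E_sed = as.numeric(E_sed), E_bio = as.numeric(E_bio),
            E_chem = as.numeric(E_chem))
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("flux magnitudes must be finite and >= 0", call. = FALSE)
  }
  structure(list(E_sed = vals[["E_sed"]], E_bio = vals[["E_bio"]],
                 E_chem = vals[["E_chem"]],
                 dGint_dt = vals[["E_sed"]] + vals[["E_bio"]] -
                   vals[["E_chem"]]),
            class = "energy_budget")
}

#' @export
print.energy_budget <- function(x, ...) {
  cat("Seafloor energy budget [J m^-2 yr^-1]\n")
  cat(sprintf("  transport    %12.4g\n  bioturbation %12.4g\n  cementation  %12.4g (enters negatively)\n",
              x$E_sed, x$E_bio, x$E_chem))
  verdict <- if (x$dGint_dt > 0) "physical energy wins: cohesion inhibited"
  else if (x$dGint_dt < 0) "chemical energy wins: cementation favored"
  else "balance point"
  cat(sprintf("  dGint/dt     %12.4g  (%s)\n", x$dGint_dt, verdict))
  invisible(x)
}

#' Physical-to-chemical energy ratio map
#'
#' Evaluates the ratio of physical energy fluxes (sediment transport plus a
#' constant bioturbation term) to the cementation flux over a grain-size by
#' shear-velocity grid:
#' \deqn{(dE_{sed}/dt + dE_{bio}/dt) / dE_{chem}/dt.}
#' Grain size acts on both sides: it sets the impact energetics and
#' threshold of motion in the numerator and the reactive surface area in
#' the denominator. Cells below the threshold of motion or in the
#' viscously damped fine-grain zone have zero transport flux, so with no
#' bioturbation their ratio is 0; any positive bioturbation sets a lower
#' bound on the ratio everywhere. Cells with ratio < 1 are
#' cementation-favorable.
#'
#' @param D_axis Monotone vector of grain diameters \[m\].
#' @param u_star_axis Monotone vector of shear velocities \[m s^-1\].
#' @param Omega Saturation state for the chemical flux; must be > 1 (at
#'   `Omega = 1` every ratio would be infinite).
#' @param bio_flux Constant bioturbation energy flux added to every cell
#'   \[J m^-2 yr^-1\].
#' @param level Label recording which bioturbation scenario `bio_flux`
#'   represents (`"none"`, `"q25"`, `"median"`, `"q75"`, `"custom"`).
#' @param phi0,L,kin,sphere_factor Passed to [cementation_energy_flux()].
#' @param H,q,rho_s,A1,duty_cycle,capacity_coef,fluid,... Passed to
#'   [sediment_energy_flux()].
#' @return A list of class `ratio_grid`: the axes, matrices `E_sed` and
#'   `ratio` (rows = grain sizes, columns = shear velocities), the vector
#'   `E_chem` along the grain-size axis, `bio_flux`, and `level`.
#' @export
#' @examples
#' rg <- ratio_map(D_axis = c(1e-4, 1e-3), u_star_axis = c(0.01, 0.1))
#' rg$ratio
ratio_map <- function(D_axis, u_star_axis, Omega = 3, bio_flux = 0,
                      level = "custom", phi0 = 0.4, L = 0.05,
                      kin = aragonite_kinetics(), sphere_factor = 1,
                      H = 1, q = "capacity", rho_s = 2850, A1 = 0.3,
                      duty_cycle = 1, capacity_coef = 0.05,
                      fluid = fluid_constants(), ...) {
  if (is.unsorted(D_axis, strictly = TRUE) ||
      is.unsorted(u_star_axis, strictly = TRUE)) {
    stop("grid axes must be strictly increasing", call. = FALSE)
  }
  if (Omega <= 1) {
    stop("Omega must be > 1: at Omega = 1 the chemical flux vanishes and ",
         "every energy ratio is infinite", call. = FALSE)
  }
  if (bio_flux < 0) stop("bio_flux must be >= 0", call. = FALSE)
  E_chem <- vapply(D_axis, function(D) {
    as.numeric(cementation_energy_flux(Omega, D, phi0, L, kin,
                                       sphere_factor))
  }, numeric(1))
  E_sed <- matrix(0, nrow = length(D_axis), ncol = length(u_star_axis),
                  dimnames = list(NULL, NULL))
  for (i in seq_along(D_axis)) {
    for (j in seq_along(u_star_axis)) {
      E_sed[i, j] <- as.numeric(sediment_energy_flux(
        u_star_axis[j], D_axis[i], H = H, q = q, rho_s = rho_s, A1 = A1,
        duty_cycle = duty_cycle, capacity_coef = capacity_coef,
        fluid = fluid, ...))
    }
  }
  ratio <- sweep(E_sed + bio_flux, 1, E_chem, "/")
  structure(list(D_axis = D_axis, u_star_axis = u_star_axis,
                 E_sed = E_sed, E_chem = E_chem, ratio = ratio,
                 bio_flux = bio_flux, level = level, Omega = Omega),
            class = "ratio_grid")
}

#' @export
print.ratio_grid <- function(x, ...) {
  cat(sprintf(
    "Energy ratio grid: %d grain sizes x %d shear velocities, Omega = %g\n",
    length(x$D_axis), length(x$u_star_axis), x$Omega))
  cat(sprintf("  bioturbation level '%s' (%g J m^-2 yr^-1)\n",
              x$level, x$bio_flux))
  cat(sprintf("  ratio range [%.3g, %.3g]; cementation-favorable fraction %.3f\n",
              min(x$ratio), max(x$ratio), cementation_favorable_fraction(x)))
  invisible(x)
}

#' Fraction of grid cells favorable for cementation
#'
#' Cells whose physical-to-chemical ratio falls below the threshold
#' (default 1, the 1:1 line) are those where cementation outcompetes the
#' physical energy fluxes.
#'
#' @param grid A [ratio_map()] result.
#' @param threshold Ratio defining "favorable" (default 1).
#' @return Fraction in \[0, 1\].
#' @export
cementation_favorable_fraction <- function(grid, threshold = 1) {
  mean(grid$ratio < threshold)
}

#' Quiet-water physical-to-chemical flux ratio
#'
#' Below the threshold of sediment motion only bioturbation opposes
#' cementation, so the relevant ratio is \eqn{F = E_{bio}/E_{chem}}.
#'
#' @param E_bio Bioturbation flux magnitude \[J m^-2 yr^-1\].
#' @param E_chem Cementation flux magnitude \[J m^-2 yr^-1\], > 0.
#' @return The dimensionless ratio F.
#' @export
#' @examples
#' quietwater_F(26.9, 403.1)  # ~0.0667
quietwater_F <- function(E_bio, E_chem) {
  if (any(E_chem <= 0)) {
    stop("E_chem must be > 0 (zero chemical flux makes F undefined)",
         call. = FALSE)
  }
  if (any(E_bio < 0)) stop("E_bio must be >= 0", call. = FALSE)
  as.numeric(E_bio) / as.numeric(E_chem)
}

#' Substrate-stability scenario: change in F between two times
#'
#' Computes \eqn{F = E_{bio}/E_{chem}} at a reference time t1 and a
#' perturbed time t2, and their ratio \eqn{\Delta F = F_{t2}/F_{t1}}.
#' Three perturbation channels mirror the mechanisms proposed for
#' end-Permian substrate stabilization, each applied through the flux
#' formulas themselves:
#' \itemize{
#'   \item `Omega`: changing saturation state scales the chemical flux by
#'     \eqn{((\Omega_2-1)/(\Omega_1-1))^n}, so
#'     \eqn{\Delta F = ((\Omega_1-1)/(\Omega_2-1))^n} (an alkalinity
#'     overshoot stabilizes substrates, F drops);
#'   \item `biomass_factor`: both bioturbation models are linear in the
#'     reworking rate R, so a biomass loss multiplies F directly;
#'   \item `bodysize_factor`: multiplies the burrow radius b; under the
#'     crack-propagation model F scales as 1/b. With
#'     `couple_depth = TRUE` the excavation model is used instead and the
#'     factor acts through the burrow depth d (F scales linearly).
#' }
#' Because every flux formula is a product of its parameters, joint
#' perturbations compose multiplicatively: the \eqn{\Delta F} of a
#' combined scenario is the product of its single-channel \eqn{\Delta F}s.
#'
#' @param Omega_t1,Omega_t2 Saturation states at the two times; both > 1.
#' @param biomass_factor Multiplier on the reworking rate R at t2.
#' @param bodysize_factor Multiplier on the burrow radius b (and depth d
#'   when `couple_depth = TRUE`) at t2.
#' @param couple_depth Apply the body-size change through the excavation
#'   model's burrow depth instead of the crack model's radius.
#' @param E_bio_t1 Reference bioturbation flux \[J m^-2 yr^-1\].
#' @param E_chem_t1 Reference chemical flux \[J m^-2 yr^-1\]; defaults to
#'   the quiet-water muddy-sediment cementation flux at `Omega_t1`.
#' @param D Grain diameter for the default reference chemical flux.
#' @param kin A [mineral_kinetics()] object (supplies the rate-law
#'   exponent).
#' @return A list of class `scenario_result` with `F_t1`, `F_t2`,
#'   `delta_F`, and the named `perturbations` applied.
#' @export
#' @examples
#' scenario_deltaF(Omega_t1 = 3, Omega_t2 = 10)      # ~1/29.9
#' scenario_deltaF(biomass_factor = 0.1)$delta_F     # 0.1
scenario_deltaF <- function(Omega_t1 = 3, Omega_t2 = Omega_t1,
                            biomass_factor = 1, bodysize_factor = 1,
                            couple_depth = FALSE,
                            E_bio_t1 = as.numeric(excavation_flux(0.1, 0.05)),
                            E_chem_t1 = NULL, D = grain_size_classes[["mud"]],
                            kin = aragonite_kinetics()) {
  if (Omega_t1 <= 1 || Omega_t2 <= 1) {
    stop("saturation states must be > 1 at both times", call. = FALSE)
  }
  if (biomass_factor <= 0 || bodysize_factor <= 0) {
    stop("perturbation factors must be > 0", call. = FALSE)
  }
  if (is.null(E_chem_t1)) {
    E_chem_t1 <- as.numeric(cementation_energy_flux(Omega_t1, D, kin = kin))
  }
  F_t1 <- quietwater_F(E_bio_t1, E_chem_t1)
  dF_omega <- ((Omega_t1 - 1) / (Omega_t2 - 1))^kin$n_exp
  dF_biomass <- biomass_factor
  dF_bodysize <- if (couple_depth) bodysize_factor else 1 / bodysize_factor
  delta_F <- dF_omega * dF_biomass * dF_bodysize
  structure(list(F_t1 = F_t1, F_t2 = F_t1 * delta_F, delta_F = delta_F,
                 perturbations = list(
                   Omega = c(t1 = Omega_t1, t2 = Omega_t2),
                   biomass_factor = biomass_factor,
                   bodysize_factor = bodysize_factor,
                   bodysize_model = if (couple_depth) "excavation"
                   else "crack_propagation")),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Substrate-stability scenario\n")
  p <- x$perturbations
  cat(sprintf("  Omega %g -> %g; biomass x%g; body size x%g (%s model)\n",
              p$Omega[["t1"]], p$Omega[["t2"]], p$biomass_factor,
              p$bodysize_factor, p$bodysize_model))
  cat(sprintf("  F_t1 = %.4g  F_t2 = %.4g  deltaF = %.4g\n",
              x$F_t1, x$F_t2, x$delta_F))
  dir <- if (x$delta_F < 1) "substrates stabilize (cementation gains)"
  else if (x$delta_F > 1) "substrates mobilize (physical energy gains)"
  else "no change"
  cat("  ", dir, "\n", sep = "")
  invisible(x)
}
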