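---
title: "An energy-balance model of carbonate seafloor cohesion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An energy-balance model of carbonate seafloor cohesion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seafloorenergy)
```

## The model

Carbonate sediments sit at a tipping point between two fates. If cement
precipitates faster than physical processes can disrupt it, grains weld
into cohesive substrates that record themselves in the rock record as
hardgrounds, flat-pebble conglomerates, and related early-lithified
fabrics. If grain impacts and burrowing animals deliver mechanical energy
faster than cements can form, the bed stays mobile. `seafloorenergy`
quantifies this competition through the interfacial free energy bound at
crystal–fluid contacts, $G_{int} = \sigma A$: cementation consumes surface
area (and thus $G_{int}$), while sediment transport and bioturbation
create it by fracturing grains and nascent cements. The balance

$$\frac{dG_{int}}{dt} = \frac{dE_{sed}}{dt} + \frac{dE_{bio}}{dt}
  - \frac{dE_{chem}}{dt}$$

is signed so that a negative rate means cementation wins. All three terms
are energy fluxes per unit seafloor area per unit time, J m⁻² yr⁻¹,
which is what makes processes as different as porewater chemistry and
whale feeding pits directly comparable. This is deliberately an
order-of-magnitude framework: each flux is an upper or lower bound built
from a small number of measurable quantities, not a process-resolving
simulation, and the three fluxes are treated as independent (bioirrigation
feedbacks of burrowers on porewater chemistry are outside its scope).

## Cementation flux

The chemical term chains four relations: surface area declines with
porosity as $A = A_0(\phi/\phi_0)^{2/3}$; porosity trades against
carbonate volume, $\phi = 1 - V_c/V_t$; precipitation follows the
empirical rate law $dV_c/dt = k(\Omega-1)^n (M_c/\rho_c) A$; and the
initial reactive area comes from the grain diameter through the specific
surface area $A_{sp} = r_f/(\rho_c D)$. Together (evaluated at the onset
of cementation, $V_c = V_{c0}$, where the surface-area decline is
steepest — the package reports this maximum rate, which
`surface_area_rate()` confirms by exposing the full attenuation term):

$$\left|\frac{dE_{chem}}{dt}\right| = \frac{2}{3}\,\sigma\,
  \frac{(A_{sp}(1-\phi_0))^2}{\phi_0}\,\rho_c M_c\, k(\Omega-1)^n L.$$

Defaults are the aragonite set: $\sigma = 0.283$ J m⁻²,
$k = 0.113$ mol m⁻² yr⁻¹, $n = 2.26$, $M_c = 0.1$ kg mol⁻¹,
$\rho_c = 2850$ kg m⁻³, roughness factor $r_f = 5$, porosity
$\phi_0 = 0.4$. The rate constant's units only close dimensionally as a
surface-normalized mol m⁻² yr⁻¹, which is how the package interprets
them. The observation window $L$ converts a volume-normalized rate to an
area-normalized one; its default, 0.05 m, is the median depth of active
bioturbation, so the chemical flux refers to the same slab of sediment
the burrowers rework. Two modeling choices are worth flagging. First,
$A_{sp}$ is implemented exactly as the inverse-diameter model prints it,
with no geometric prefactor; an ideal sphere would carry a factor 6, and
a `sphere_factor` argument exposes that alternative without changing the
default. Second, the rate law is precipitation-only: $\Omega < 1$ is a
domain error rather than a negative flux, because the constants were fit
to precipitation experiments.

Two consequences of the closed form anchor the test suite: the flux
scales as $D^{-2}$ (fine muds cement an order of magnitude faster per
decade of grain size), and the ratio between two saturation states
collapses to the rate law alone,
$(\Omega_2-1)^n/(\Omega_1-1)^n$. For the canonical pair
$\Omega = 3$ (modern tropical surface seawater) and $\Omega = 10$
(anoxic porewaters, and a proposed state of earlier Phanerozoic basins)
that ratio is $(9/2)^{2.26} = 29.94$ — about one and a half orders of
magnitude. The package computes 29.94 and makes no attempt to force the
looser "approximately one order of magnitude" phrasing sometimes applied
to this comparison; both statements refer to the same rate law.

## Sediment transport flux

The kinetic term is an energy-delivery rate obtained by truncating a
grain-impact abrasion model at the point where energy, rather than eroded
volume, is the quantity of interest:

$$\frac{dE_{sed}}{dt} = \frac{1}{2}\,
  \frac{A_1 \rho_c\, q\, w_i^3}{U H \chi + U_b H_b},$$

with efficiency $A_1 = 0.3$. For the dimensions to close to an energy
flux, $q$ must be the volumetric sediment supply per unit flow width
(m² s⁻¹); $\rho_c q$ is then the mass supply the impacting grains
represent. The surrounding submodels are not prescribed by the headline
equation, so each is a declared, configurable choice with a
literature-standard default:

* **Settling velocity** — Ferguson–Church closed form
  ($C_1 = 18$, $C_2 = 1$), which is the harmonic junction of the Stokes
  and turbulent-drag asymptotes.
* **Threshold of motion** — Shields number
  $\tau^* = \rho_w u_*^2/((\rho_s-\rho_w) g D)$ against the explicit
  Brownlie fit of the Shields curve (a constant 0.03 is available via
  configuration). Below threshold the flux is identically zero.
* **Bedload layer** — transport-stage scalings
  $H_b = 1.44 D (\tau^*/\tau^*_c)^{0.5}$ (capped at the flow depth) and
  $U_b = 1.56\sqrt{R'gD}(\tau^*/\tau^*_c)^{0.56}$.
* **Suspension integral** — $\chi$ is the depth-integrated overlap of the
  log-law velocity profile ($z_0 = D/30$, $\kappa = 0.41$) and the Rouse
  concentration profile with Rouse number $P = w_s/(\kappa u_*)$,
  normalized by $UH$; evaluated by adaptive quadrature at relative
  tolerance $10^{-8}$ and cross-checked in tests against a $10^5$-point
  midpoint sum.
* **Viscous damping** — impacts are transmitted only above a particle
  Stokes number $St = (\rho_s/9\rho_w)\, w_s D/\nu$ of 30, fully above
  75, with a linear ramp between. Under the defaults this silences
  grains finer than roughly a millimetre — the fine-grained
  cementation-favorable edge of the regime maps.
* **Sediment supply** — `q = "capacity"` (default) uses an
  Engelund–Hansen-type relation $q = 0.05\, u_*^5/(R'^2 g^2 D)$,
  equivalent to $q^* = 0.05\,\tau^{*\,2.5}$, which also makes the flux go
  continuously to zero at the threshold. A user-fixed $q$ instead jumps
  there; that discontinuity is documented behavior.

Flow depth defaults to $H = 1$ m and fluxes are while-transporting rates:
storm intermittency is exposed only as an optional `duty_cycle`
multiplier (default 1). Because every submodel beyond the headline
equation is a declared default rather than a published closure, the
*positions* of ratio-map contours are package-specific; the structural
features (threshold edge, damped zone, monotone response to bioturbation)
are the reliable outputs.

## Bioturbation fluxes

Bioturbation is represented by two end members that bracket the
mechanical work real burrowers do. *Gravitational excavation* is the
lower bound: an upward-conveyor must at minimum lift excavated sediment
against gravity, giving
$dE_{gr}/dt = \tfrac12 (1-\phi)(\rho_s-\rho_w) R g d$
(the closed form equals raising the burrow's buoyant mass from half its
depth, which `excavation_work()` verifies against a discrete slab-by-slab
Riemann sum — midpoint slabs are exact because the integrand is linear,
left-endpoint sums converge as $1/n$). *Crack propagation* is the upper
bound: burrowing through cohesive mud by fracture costs
$dE_{cr}/dt = 2 G_c R/(\pi b)$, where $b$ is the burrow *radius* — the
derivation that produces the factor $2/\pi$ defines $b$ as half the
burrow width, and the package follows that definition even where looser
descriptions call $b$ the width. The default fracture toughness,
$G_c = 1$ J m⁻², is an order-of-magnitude value for cohesive marine
muds and is configurable per record. Both models are linear in the
population-level volumetric reworking rate $R$ (m³ m⁻² yr⁻¹), which is
what makes compiled reworking-rate datasets directly usable.

## The synthetic reworking table

`synthesize_reworking_table()` emulates a compiled, group-structured
table of population reworking rates of the kind assembled from the
benthic ecology literature. Six groups span the observed range: deep
infaunal molluscs ($R$ up to $10^3$ m³ m⁻² yr⁻¹, burrows 0.28–0.6 m),
crustaceans (callianassid-style deep shrimp to shallow crabs),
polychaetes, echinoderms, holothurians, and macro-epifauna (whale and
ray feeding pits: individually large excavations, 0.16–0.20 m deep, but
population rates suppressed to $10^{-6}$–$10^{-3}$ by low densities).
Macro-epifauna are excavation-only — brief surface interactions do not
propagate fractures — while the infaunal groups support both end
members, with per-record $G_c$ drawn log-uniformly from 1–10 J m⁻².

Within each group, $R$ is drawn log-uniformly with one draw per equal
log₁₀ stratum (50 taxa per group by default), so a realized table always
covers its group's full range; radius, depth, and toughness are plain
log-uniform draws. The stratification is what makes the table's headline
property structural rather than lucky: the top mollusc stratum and the
bottom macro-epifauna stratum guarantee that excavation fluxes span at
least nine decades, while the shallow depth floor of the epifauna keeps
the whole comparison — both bioturbation models plus the chemical bands
from mud to coarse sand at $\Omega \in \{3, 10\}$ — just under ten
decades. One side effect: the pooled burrow-depth median lands near
0.06–0.08 m rather than exactly at the 0.05 m the observation-window
default $L$ is based on; $L$ stays at 0.05 m, and the small mismatch is
accepted rather than distorting the group geometries. What the synthetic
table does *not* emulate: real taxon identities, abundance-weighted
sampling, covariance between body size and reworking rate, or
within-taxon seasonal variability — so passing tests say the *flux
machinery and its distributional envelope* behave, not that any
particular modern community is reproduced. A real table in the same
schema (CSV or XLSX: `taxon`, `group`, `reworking_rate`,
`burrow_radius`, `burrow_depth`, optional `mode` and
`fracture_toughness`) drops in through `read_reworking_table()`.

```{r spans}
f2 <- run_figure2()
c(bio = f2$bio_span_decades, all = f2$span_decades)
```

## Ratio maps and scenarios

`ratio_map()` evaluates
$(dE_{sed}/dt + dE_{bio}/dt)/(dE_{chem}/dt)$ on a grain-size ×
shear-velocity grid; grain size enters both the numerator (threshold,
damping, impact energy) and the denominator ($A_{sp}^2$). Cells below 1
are cementation-favorable; the contour levels $\{0.01, 1, 100\}$ are a
plotting convention, with 1 the physically meaningful line.
`run_figure3()` steps a constant bioturbation term through the pooled
quartiles of the excavation-model fluxes of a reworking table (the lower
end member is the conservative choice for scenario thresholds; quantiles
are type-7 linear interpolation so thresholds are bit-reproducible). The
favorable area shrinks monotonically by construction — adding a larger
constant to every numerator can only raise ratios — and the default grid
shows it shrinking from ~85 % to ~22 % of the plane.

```{r fig3}
f3 <- run_figure3()
f3$favorable_fraction
```

For quiet-water settings below the threshold of motion the balance
reduces to $F = E_{bio}/E_{chem}$, and changes between two times to
$\Delta F = F_{t2}/F_{t1}$. Because every flux formula is a product of
its parameters, the three perturbation channels compose
multiplicatively and can be read as one-parameter vectors: a saturation
change scales $\Delta F$ by $((\Omega_1-1)/(\Omega_2-1))^n$, a biomass
change acts linearly through $R$, and a body-size change acts through
the crack model's $1/b$ (or, with `couple_depth = TRUE`, through the
excavation model's $d$). The choice of which end-member model carries
the body-size channel is genuinely open; the crack model is the default
because burrow radius appears in it explicitly, and the output records
which model was used. Quantitative vector lengths for any particular
extinction scenario depend on scaling assumptions (biomass loss
fractions, alkalinity trajectories) that must be supplied by the user;
the package deliberately exposes only the three multiplier channels.

```{r scenario}
scenario_deltaF(Omega_t1 = 3, Omega_t2 = 10)$delta_F
scenario_deltaF(biomass_factor = 0.1)$delta_F
```

## Numerical choices and degenerate inputs

* The canonical time unit is the year (the rate constant's unit);
  hydraulic submodels compute in seconds and convert once, at the flux
  boundary, via `seconds_per_year` ($3.156\times 10^7$), avoiding silent
  $3\times10^7$-fold errors.
* The suspension quadrature reports its offending parameters on
  non-convergence rather than returning a value.
* Zero is exact where physics says so: $\Omega = 1$, $R = 0$, $q = 0$,
  sub-threshold shear, fully damped impacts all return exactly 0, not a
  small number.
* Degenerate geometry is rejected loudly: $\phi > \phi_0$,
  $V_c \ge V_t$, $H_b \ge H$, $\rho_s \le \rho_w$, non-positive
  diameters and radii are all errors with targeted messages, as are
  unknown configuration keys.
* Default problem sizes: 300 synthetic taxa (6 × 50) and a 60 × 60
  ratio-map grid, chosen as the coarsest sizes at which the
  distributional spans and map structure are stable; tests use smaller
  grids where only structure is asserted.

## Limitations

The framework compares *capacities* to deliver energy, not realized
geological outcomes: it has no time dimension beyond the fluxes
themselves, no feedback of cementation on erodibility or of burrowing on
porewater chemistry, no wave-driven oscillatory transport, no
dissolution, and its transport submodels are declared conventions rather
than site calibrations. Ratio-map contour positions should be read as
order-of-magnitude geography, and absolute scenario vectors require
user-supplied scalings. Within those bounds, the structural results —
which flux dominates where, and how perturbations shift the balance —
are robust to the configurable details.
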