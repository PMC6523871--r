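#' Two-pore capillary wall description
#'
#' Parameters of the two-pore formalism for transcapillary solute exchange:
#' a population of small pores and a sparse population of large pores in the
#' capillary wall. A fraction `alpha_large` of the wall's hydraulic
#' conductance is attributed to the large pores. On top of the net
#' filtration (lymph) flow, an isogravimetric circular fluid flux
#' recirculates through the large pores and back through the small pores;
#' it is parameterised here as a fraction of the organ lymph flow.
#'
#' @param small_pore_radius Small pore radius (nm, default 4.5).
#' @param large_pore_radius Large pore radius (nm, default 25).
#' @param alpha_large Fraction of hydraulic conductance through large pores
#'   (default 0.05).
#' @param isogravimetric_flux_fraction Circular (isogravimetric) fluid flux
#'   as a fraction of organ lymph flow (default 0.5).
#' @param plasma_viscosity Plasma viscosity (mPa s, default 1.2).
#' @param net_filtration_pressure Net transcapillary filtration pressure
#'   (mmHg, default 1) used to anchor the wall's hydraulic conductance to
#'   the organ lymph flow.
#' @param temperature Absolute temperature (K, default 310.15) for the
#'   Stokes-Einstein free diffusion coefficient.
#' @return An object of class `pore_system`.
#' @export
pore_system <- function(small_pore_radius = 4.5,
                        large_pore_radius = 25,
                        alpha_large = 0.05,
                        isogravimetric_flux_fraction = 0.5,
                        plasma_viscosity = 1.2,
                        net_filtration_pressure = 1,
                        temperature = 310.15) {
  if (small_pore_radius <= 0 || large_pore_radius <= 0)
    stop("pore radii must be strictly positive")
  if (small_pore_radius >= large_pore_radius)
    stop("small_pore_radius must be below large_pore_radius")
  if (alpha_large <= 0 || alpha_large >= 1)
    stop("alpha_large must lie strictly in (0, 1)")
  if (isogravimetric_flux_fraction < 0)
    stop("isogravimetric_flux_fraction must be non-negative")
  if (isogravimetric_flux_fraction > 1 - alpha_large)
    stop("isogravimetric_flux_fraction would drive the small-pore fluid ",
         "flux negative (must be <= 1 - alpha_large)")
  if (plasma_viscosity <= 0 || net_filtration_pressure <= 0 || temperature <= 0)
    stop("viscosity, filtration pressure and temperature must be positive")
  structure(list(small_pore_radius = small_pore_radius,
                 large_pore_radius = large_pore_radius,
                 alpha_large = alpha_large,
                 isogravimetric_flux_fraction = isogravimetric_flux_fraction,
                 plasma_viscosity = plasma_viscosity,
                 net_filtration_pressure = net_filtration_pressure,
                 temperature = temperature),
            class = "pore_system")
}

#' Steric hindrance factors for a solute in a cylindrical pore
#'
#' For a solute-to-pore radius ratio a = r_solute/r_pore the partition
#' coefficient is Phi = (1 - a)^2, the diffusive hindrance is
#' Phi * (1 - 2.104 a + 2.09 a^3 - 0.95 a^5) (Renkin), floored at 0, and the
#' osmotic reflection coefficient is sigma = 1 - Phi (2 - Phi)(1 - a^2/3),
#' clamped to [0, 1]. A solute at least as large as the pore is fully
#' excluded: Phi = 0, hindrance = 0, sigma = 1.
#'
#' @param solute_radius Solute (particle) radius (nm).
#' @param pore_radius Pore radius (nm).
#' @return List with `partition_coefficient`, `diffusive_hindrance` and
#'   `reflection_coefficient`.
#' @export
pore_hindrances <- function(solute_radius, pore_radius) {
  if (solute_radius <= 0 || pore_radius <= 0)
    stop("solute and pore radii must be strictly positive")
  a <- solute_radius / pore_radius
  if (a >= 1)
    return(list(partition_coefficient = 0,
                diffusive_hindrance = 0,
                reflection_coefficient = 1))
  phi <- (1 - a)^2
  hind <- phi * (1 - 2.104 * a + 2.09 * a^3 - 0.95 * a^5)
  hind <- max(hind, 0)
  sigma <- 1 - phi * (2 - phi) * (1 - a^2 / 3)
  sigma <- min(max(sigma, 0), 1)
  list(partition_coefficient = phi,
       diffusive_hindrance = hind,
       reflection_coefficient = sigma)
}

#' Fluid fluxes through the small and large pore pathways
#'
#' Splits an organ's net transcapillary filtration (equal to its lymph flow
#' L at steady state) between the two pore classes and superimposes the
#' isogravimetric circular flux J_iso = fraction * L:
#' J_large = alpha_large * L + J_iso and
#' J_small = (1 - alpha_large) * L - J_iso, so J_small + J_large = L exactly.
#'
#' @param lymph_flow Organ lymph flow L (mL/h).
#' @param pores A [pore_system()].
#' @return List with `J_small` and `J_large` (mL/h).
#' @export
pore_fluid_fluxes <- function(lymph_flow, pores = pore_system()) {
  if (lymph_flow < 0) stop("lymph_flow must be non-negative")
  J_iso <- pores$isogravimetric_flux_fraction * lymph_flow
  J_large <- pores$alpha_large * lymph_flow + J_iso
  J_small <- (1 - pores$alpha_large) * lymph_flow - J_iso
  if (J_small < 0)
    stop("pore configuration yields a negative small-pore fluid flux")
  list(J_small = J_small, J_large = J_large)
}

# Stokes-Einstein free diffusion coefficient, cm^2/h, for a solute radius in
# nm at the pore system's temperature and plasma viscosity.
.free_diffusion <- function(solute_radius, pores) {
  kB <- 1.380649e-23                       # J/K
  eta <- pores$plasma_viscosity * 1e-3     # mPa s -> Pa s
  r <- solute_radius * 1e-9                # nm -> m
  D <- kB * pores$temperature / (6 * pi * eta * r)  # m^2/s
  D * 1e4 * 3600                           # -> cm^2/h
}

#' Permeability-surface area product of one pore class
#'
#' The pore pathway's effective area-over-path (A0/dx) is anchored to the
#' organ's hydraulic conductance: the wall conductance is L / dP (organ
#' lymph flow over net filtration pressure), the pore class receives its
#' hydraulic share, and Poiseuille flow in cylindrical pores converts the
#' share to a geometric A0/dx = 8 eta Lp / r^2. Then
#' PS = (A0/dx) * D_free * diffusive_hindrance, with D_free from the
#' Stokes-Einstein relation. PS is 0 when the solute does not fit the pore.
#'
#' @param pore_radius Pore radius (nm).
#' @param fluid_conductance_share This pore class's share of the organ
#'   hydraulic conductance times the organ lymph flow, i.e. its share of the
#'   net filtration (mL/h).
#' @param solute_radius Solute radius (nm).
#' @param pores A [pore_system()].
#' @return Permeability-surface area product PS (mL/h).
#' @export
permeability_surface <- function(pore_radius, fluid_conductance_share,
                                 solute_radius, pores = pore_system()) {
  if (pore_radius <= 0 || solute_radius <= 0)
    stop("radii must be strictly positive")
  if (fluid_conductance_share < 0)
    stop("fluid_conductance_share must be non-negative")
  h <- pore_hindrances(solute_radius, pore_radius)
  if (h$diffusive_hindrance == 0) return(0)
  eta <- pores$plasma_viscosity * 1e-3                  # Pa s
  dP <- pores$net_filtration_pressure * 133.322         # mmHg -> Pa
  Q <- fluid_conductance_share * 1e-6 / 3600            # mL/h -> m^3/s
  Lp <- Q / dP                                          # m^3/(s Pa)
  r_m <- pore_radius * 1e-9
  A0_dx <- 8 * eta * Lp / r_m^2                         # m
  D <- .free_diffusion(solute_radius, pores) / 1e4 / 3600  # cm^2/h -> m^2/s
  PS <- A0_dx * D * h$diffusive_hindrance               # m^3/s
  PS * 1e6 * 3600                                       # -> mL/h
}

#' Patlak flux across one pore pathway
#'
#' Net solute mass flux from plasma to interstitium through one pore class,
#' combining convection and diffusion:
#' Pe = J (1 - sigma) / PS,
#' flux = J (1 - sigma) (C_p - C_i e^{-Pe}) / (1 - e^{-Pe}).
#' Numerically stable for Pe -> 0 (pure diffusion, PS (C_p - C_i)) and
#' Pe -> Inf (pure convection, J (1 - sigma) C_p); Pe is capped at 700.
#'
#' @param C_plasma Plasma concentration (ug/mL).
#' @param C_interstitial Interstitial concentration (ug/mL).
#' @param J Fluid flux through this pore class (mL/h).
#' @param PS Permeability-surface area product (mL/h).
#' @param sigma Reflection coefficient of this pore class.
#' @return Mass flux (ug/h), positive from plasma to interstitium.
#' @export
patlak_solute_flux <- function(C_plasma, C_interstitial, J, PS, sigma) {
  if (C_plasma < 0 || C_interstitial < 0)
    stop("concentrations must be non-negative")
  Jeff <- J * (1 - sigma)
  if (PS <= 0) {
    if (Jeff == 0) return(0)           # fully excluded pathway
    return(Jeff * C_plasma)            # pure convection
  }
  if (Jeff == 0) return(PS * (C_plasma - C_interstitial))
  Pe <- Jeff / PS
  # cap only the exponent: beyond Pe ~ 700 the pathway is purely convective
  em <- expm1(-min(Pe, 700))           # e^{-Pe} - 1
  Jeff * (C_plasma - C_interstitial * (1 + em)) / (-em)
}

#' Lymph drainage flux from the interstitial space
#'
#' Solute leaves the interstitial space with lymph flow, partially reflected
#' by the extracellular matrix: flux = (1 - sigma_IS) L C_i.
#'
#' @param C_interstitial Interstitial concentration (ug/mL).
#' @param lymph_flow Organ lymph flow (mL/h).
#' @param sigma_IS Lymph reflection coefficient in [0, 1].
#' @return Mass flux into the lymph (ug/h).
#' @export
lymph_drainage_flux <- function(C_interstitial, lymph_flow, sigma_IS) {
  if (sigma_IS < 0 || sigma_IS > 1)
    stop("sigma_IS must lie in [0, 1]")
  if (C_interstitial < 0) stop("concentration must be non-negative")
  (1 - sigma_IS) * lymph_flow * C_interstitial
}

#' Organ-level two-pore transport coefficients
#'
#' Precomputes, for each pore class of one organ, the fluid flux, the
#' permeability-surface area product and the reflection coefficient for a
#' given solute radius.
#'
#' @param solute_radius Particle hydrodynamic radius (nm).
#' @param lymph_flow Organ lymph flow (mL/h).
#' @param pores A [pore_system()].
#' @return List with elements `small` and `large`, each holding `J`, `PS`,
#'   `sigma`, `partition_coefficient`, plus `Pe` at the precomputed fluxes.
#' @export
pore_transport_coefficients <- function(solute_radius, lymph_flow,
                                        pores = pore_system()) {
  fl <- pore_fluid_fluxes(lymph_flow, pores)
  mk <- function(r_pore, J, share) {
    h <- pore_hindrances(solute_radius, r_pore)
    PS <- permeability_surface(r_pore, share, solute_radius, pores)
    Jeff <- J * (1 - h$reflection_coefficient)
    list(J = J, PS = PS, sigma = h$reflection_coefficient,
         partition_coefficient = h$partition_coefficient,
         Pe = if (PS > 0) Jeff / PS else Inf)
  }
  # Hydraulic shares: large pores alpha_large of conductance, small pores
  # the remainder; shares expressed as fractions of the net filtration L.
  list(
    small = mk(pores$small_pore_radius, fl$J_small,
               (1 - pores$alpha_large) * lymph_flow),
    large = mk(pores$large_pore_radius, fl$J_large,
               pores$alpha_large * lymph_flow)
  )
}
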