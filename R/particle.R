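#' Nanoparticle physicochemical properties
#'
#' Container for the characterization data of a nanoparticle formulation.
#' The hydrodynamic diameter (DLS) includes the metal core, capping agent
#' and solvent layer and drives transcapillary transport; the core diameter
#' (TEM) drives the mass-to-number conversion. Polydispersity index and zeta
#' potential are carried as informational metadata only.
#'
#' @param label Formulation name.
#' @param hydrodynamic_diameter Hydrodynamic diameter (nm).
#' @param core_diameter Metal core diameter (nm).
#' @param polydispersity_index Dimensionless PDI (informational).
#' @param zeta_potential Zeta potential (mV, informational).
#' @param mass_concentration Gold mass concentration of the stock (ug Au/mL).
#' @param gold_density Density of bulk gold (g/cm^3, default 19.3).
#' @return An object of class `particle_properties`.
#' @examples
#' p <- particle_properties("EGCG-AuNP", 25.00, 7.78,
#'                          mass_concentration = 422.79)
#' solute_radius(p)  # 12.5 nm
#' @export
particle_properties <- function(label = "AuNP",
                                hydrodynamic_diameter,
                                core_diameter = hydrodynamic_diameter,
                                polydispersity_index = NA_real_,
                                zeta_potential = NA_real_,
                                mass_concentration = 0,
                                gold_density = 19.3) {
  if (!is.numeric(hydrodynamic_diameter) || hydrodynamic_diameter < 0)
    stop("hydrodynamic_diameter must be non-negative (nm)")
  if (!is.numeric(core_diameter) || core_diameter < 0)
    stop("core_diameter must be non-negative (nm)")
  if (core_diameter > hydrodynamic_diameter)
    stop("core_diameter cannot exceed hydrodynamic_diameter")
  if (mass_concentration < 0) stop("mass_concentration must be non-negative")
  if (gold_density <= 0) stop("gold_density must be positive")
  structure(list(label = label,
                 hydrodynamic_diameter = hydrodynamic_diameter,
                 core_diameter = core_diameter,
                 polydispersity_index = polydispersity_index,
                 zeta_potential = zeta_potential,
                 mass_concentration = mass_concentration,
                 gold_density = gold_density),
            class = "particle_properties")
}

#' Hydrodynamic (solute) radius of a particle
#'
#' Half the hydrodynamic diameter; the key particle input to the two-pore
#' extravasation model.
#'
#' @param p A [particle_properties()] object.
#' @return Radius in nm.
#' @export
solute_radius <- function(p) {
  if (p$hydrodynamic_diameter <= 0)
    stop("hydrodynamic_diameter must be strictly positive")
  p$hydrodynamic_diameter / 2
}

#' Particle number concentration from mass concentration
#'
#' Converts a gold mass concentration to a particle number concentration
#' assuming spherical cores of bulk gold density:
#' N = C_mass / (rho * (pi/6) * d_core^3).
#'
#' @param p A [particle_properties()] object with positive `core_diameter`.
#' @return Particles per mL.
#' @examples
#' p <- particle_properties("Curc-AuNP", 19.62, 6.21,
#'                          mass_concentration = 391.43)
#' number_concentration(p)  # ~1.6e14 AuNP/mL
#' @export
number_concentration <- function(p) {
  if (p$core_diameter <= 0)
    stop("core_diameter must be strictly positive for number concentration")
  d_cm <- p$core_diameter * 1e-7            # nm -> cm
  mass_per_particle_ug <- p$gold_density * (pi / 6) * d_cm^3 * 1e6  # g -> ug
  p$mass_concentration / mass_per_particle_ug
}

#' Renal clearance of a particle
#'
#' Renal excretion is negligible for particles larger than 10 nm in
#' hydrodynamic diameter; for smaller particles a configured glomerular
#' clearance applies (default 0).
#'
#' @param p A [particle_properties()] object.
#' @param small_particle_clearance Glomerular clearance (mL/h) applied when
#'   the hydrodynamic diameter is 10 nm or less.
#' @return Clearance in mL/h.
#' @export
renal_clearance_switch <- function(p, small_particle_clearance = 0) {
  if (p$hydrodynamic_diameter <= 0)
    stop("hydrodynamic_diameter must be strictly positive")
  if (p$hydrodynamic_diameter > 10) 0 else small_particle_clearance
}

#' @export
print.particle_properties <- function(x, ...) {
  cat(sprintf("<particle_properties> %s\n", x$label))
  cat(sprintf("  hydrodynamic diameter: %.4g nm (radius %.4g nm); core: %.4g nm\n",
              x$hydrodynamic_diameter, x$hydrodynamic_diameter / 2,
              x$core_diameter))
  if (x$mass_concentration > 0)
    cat(sprintf("  stock: %.4g ug Au/mL (%.3g AuNP/mL)\n",
                x$mass_concentration,
                if (x$core_diameter > 0) number_concentration(x) else NA))
  invisible(x)
}
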