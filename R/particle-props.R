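#' Primary particle specification
#'
#' Describes a monodisperse primary (constituent) particle. Units follow the
#' conventions of experimental nanotoxicology: diameters in nanometres,
#' densities in g/cm^3. All internal physics converts to SI.
#'
#' @param diameter_nm primary particle diameter (nm), e.g. 13 for the
#'   TEM-sized SPIO (magnetite) particle the packaged defaults describe
#' @param density_g_cm3 particle material density (g/cm^3); magnetite is 5.2
#' @return an object of class `particle_spec`
#' @examples
#' spio_particle()
#' @export
particle_spec <- function(diameter_nm, density_g_cm3) {
  .check_positive(diameter_nm, "diameter_nm")
  .check_positive(density_g_cm3, "density_g_cm3")
  structure(list(diameter_nm = diameter_nm, density_g_cm3 = density_g_cm3),
            class = c("particle_spec", "particledose_spec"))
}

#' Fractal agglomerate specification
#'
#' In protein-containing culture media, primary nanoparticles form fractal
#' agglomerates whose hydrodynamic size (from DLS) far exceeds the primary
#' size. The agglomerate is characterised by a fractal dimension `DF`
#' (1 < DF <= 3) and a packing factor `PF` (0 < PF <= 1); together with the
#' size ratio these determine how many primary particles an agglomerate
#' holds and how much of its volume is solid.
#'
#' @param hydrodynamic_diameter_nm agglomerate hydrodynamic diameter (nm);
#'   must be >= the primary diameter
#' @param fractal_dimension dimensionless fractal dimension, in (1, 3]
#' @param packing_factor dimensionless packing factor, in (0, 1]; 0.637 is
#'   random close packing of spheres
#' @param primary a [particle_spec()]
#' @return an object of class `agglomerate_spec`
#' @examples
#' spio_agglomerate()
#' @export
agglomerate_spec <- function(hydrodynamic_diameter_nm, fractal_dimension,
                             packing_factor, primary) {
  stopifnot(inherits(primary, "particle_spec"))
  .check_positive(hydrodynamic_diameter_nm, "hydrodynamic_diameter_nm")
  if (hydrodynamic_diameter_nm < primary$diameter_nm) {
    abort("`hydrodynamic_diameter_nm` must be >= the primary particle diameter")
  }
  if (!(fractal_dimension > 1 && fractal_dimension <= 3)) {
    abort("`fractal_dimension` must lie in (1, 3]")
  }
  if (!(packing_factor > 0 && packing_factor <= 1)) {
    abort("`packing_factor` must lie in (0, 1]")
  }
  structure(list(hydrodynamic_diameter_nm = hydrodynamic_diameter_nm,
                 fractal_dimension = fractal_dimension,
                 packing_factor = packing_factor,
                 primary = primary),
            class = c("agglomerate_spec", "particledose_spec"))
}

#' Suspension medium specification
#'
#' @param density_g_cm3 medium density (g/cm^3)
#' @param viscosity_pa_s dynamic viscosity (Pa s); serum-supplemented RPMI at
#'   37 C is about 0.00074
#' @param temperature_k absolute temperature (K)
#' @return an object of class `medium_spec`
#' @examples
#' rpmi_medium()
#' @export
medium_spec <- function(density_g_cm3 = 1.0, viscosity_pa_s = 0.00074,
                        temperature_k = 310) {
  .check_positive(density_g_cm3, "density_g_cm3")
  .check_positive(viscosity_pa_s, "viscosity_pa_s")
  .check_positive(temperature_k, "temperature_k")
  structure(list(density_g_cm3 = density_g_cm3,
                 viscosity_pa_s = viscosity_pa_s,
                 temperature_k = temperature_k),
            class = c("medium_spec", "particledose_spec"))
}

#' Lognormal aerosol size distribution
#'
#' A single lognormal mode summarised by its count median diameter (CMD) and
#' geometric standard deviation (GSD), with the aerosol mass concentration
#' and (optionally) the effective density of the airborne agglomerates.
#'
#' @param cmd_nm count median diameter (nm)
#' @param gsd geometric standard deviation (dimensionless, >= 1)
#' @param mass_concentration_mg_m3 aerosol mass concentration (mg/m^3)
#' @param effective_density_g_cm3 optional effective particle density (g/cm^3)
#' @return an object of class `aerosol_distribution`
#' @export
aerosol_distribution <- function(cmd_nm, gsd, mass_concentration_mg_m3 = 0,
                                 effective_density_g_cm3 = NULL) {
  .check_positive(cmd_nm, "cmd_nm")
  if (!(is.numeric(gsd) && length(gsd) == 1 && gsd >= 1)) {
    abort("`gsd` must be a single number >= 1")
  }
  .check_positive(mass_concentration_mg_m3, "mass_concentration_mg_m3",
                  strict = FALSE)
  structure(list(cmd_nm = cmd_nm, gsd = gsd,
                 mass_concentration_mg_m3 = mass_concentration_mg_m3,
                 effective_density_g_cm3 = effective_density_g_cm3),
            class = c("aerosol_distribution", "particledose_spec"))
}

#' Packaged default specifications
#'
#' Convenience constructors carrying the SPIO (superparamagnetic iron oxide,
#' magnetite) particle, its agglomerate in serum-supplemented RPMI, the
#' medium itself, and the exposure aerosol, as read from the packaged default
#' configuration.
#'
#' @return the corresponding specification object
#' @name defaults
NULL

#' @rdname defaults
#' @export
spio_particle <- function() particle_spec(13, 5.2)

#' @rdname defaults
#' @export
spio_agglomerate <- function() {
  agglomerate_spec(276, 2.1, 0.637, spio_particle())
}

#' @rdname defaults
#' @export
rpmi_medium <- function() medium_spec(1.0, 0.00074, 310)

#' @rdname defaults
#' @export
spio_aerosol <- function() aerosol_distribution(68.6, 1.65, 19.9, 5.2)

#' Number of primary particles per fractal agglomerate
#'
#' Sterling's relation for a fractal agglomerate:
#' `N = PF * (d_agg / d_p)^DF`. For a space-filling packing (`DF = 3`,
#' `PF = 1`) this reduces to the volume ratio of the two spheres.
#'
#' @param agg an [agglomerate_spec()]
#' @return number of primary particles (dimensionless count, >= PF)
#' @examples
#' particles_per_agglomerate(spio_agglomerate())  # about 390
#' @export
particles_per_agglomerate <- function(agg) {
  stopifnot(inherits(agg, "agglomerate_spec"))
  ratio <- agg$hydrodynamic_diameter_nm / agg$primary$diameter_nm
  with_unit(agg$packing_factor * ratio^agg$fractal_dimension, "count")
}

#' Effective density of a fractal agglomerate in suspension
#'
#' The agglomerate is mostly medium: its solid volume fraction is
#' `phi = N * (d_p / d_agg)^3` and the effective density interpolates
#' between medium and solid, `rho_eff = rho_f + (rho_p - rho_f) * phi`.
#' Effective density, not material density, drives gravitational settling of
#' agglomerated nanoparticles in culture media.
#'
#' @param agg an [agglomerate_spec()]
#' @param medium a [medium_spec()]
#' @return effective density (g/cm^3), bounded by the medium and solid
#'   densities
#' @examples
#' effective_density(spio_agglomerate(), rpmi_medium())  # about 1.17
#' @export
effective_density <- function(agg, medium) {
  stopifnot(inherits(agg, "agglomerate_spec"), inherits(medium, "medium_spec"))
  N <- as.numeric(particles_per_agglomerate(agg))
  phi <- N * (agg$primary$diameter_nm / agg$hydrodynamic_diameter_nm)^3
  rho <- medium$density_g_cm3 +
    (agg$primary$density_g_cm3 - medium$density_g_cm3) * phi
  with_unit(rho, "g/cm^3")
}

#' Stokes-Einstein diffusion coefficient
#'
#' `D = kB * T / (3 * pi * mu * d)` for a sphere of hydrodynamic diameter
#' `d` in a medium of viscosity `mu` at temperature `T`.
#'
#' @param diameter_nm hydrodynamic diameter (nm)
#' @param medium a [medium_spec()]
#' @return diffusion coefficient (m^2/s)
#' @examples
#' diffusion_coefficient(276, rpmi_medium())  # about 2.2e-12 m^2/s
#' @export
diffusion_coefficient <- function(diameter_nm, medium) {
  stopifnot(inherits(medium, "medium_spec"))
  .check_positive(diameter_nm, "diameter_nm")
  d_m <- diameter_nm * 1e-9
  D <- .kB * medium$temperature_k / (3 * pi * medium$viscosity_pa_s * d_m)
  with_unit(D, "m^2/s")
}

#' Stokes settling velocity
#'
#' `V = g * d^2 * (rho_eff - rho_f) / (18 * mu)`, positive downward. Buoyant
#' particles (effective density below the medium) give a negative velocity;
#' the transport solver handles them, with delivery then diffusion-dominated.
#'
#' @param diameter_nm hydrodynamic diameter (nm)
#' @param effective_density_g_cm3 agglomerate effective density (g/cm^3)
#' @param medium a [medium_spec()]
#' @return settling velocity (m/s), positive toward the cell plane
#' @examples
#' rho <- effective_density(spio_agglomerate(), rpmi_medium())
#' sedimentation_velocity(276, rho, rpmi_medium())  # about 9.6e-9 m/s
#' @export
sedimentation_velocity <- function(diameter_nm, effective_density_g_cm3,
                                   medium) {
  stopifnot(inherits(medium, "medium_spec"))
  .check_positive(diameter_nm, "diameter_nm")
  d_m <- diameter_nm * 1e-9
  drho <- (effective_density_g_cm3 - medium$density_g_cm3) * 1000  # kg/m^3
  V <- .g0 * d_m^2 * drho / (18 * medium$viscosity_pa_s)
  with_unit(as.numeric(V), "m/s")
}

#' Convert particle mass to particle number and surface area
#'
#' For monodisperse solid spheres, a mass `m` contains
#' `m / (rho * pi * d^3 / 6)` particles presenting a total surface area of
#' `m * 6 / (rho * d)`. For the 13 nm, 5.2 g/cm^3 packaged particle this
#' gives about 1.67e5 particles and 8.87e-7 cm^2 per picogram.
#'
#' @param mass_pg particle mass (pg); vectorised
#' @param particle a [particle_spec()]
#' @return a tibble with columns `mass_pg`, `number`, `surface_area_cm2`
#' @examples
#' mass_number_surface_convert(1, spio_particle())
#' @export
mass_number_surface_convert <- function(mass_pg, particle) {
  stopifnot(inherits(particle, "particle_spec"))
  if (any(mass_pg < 0)) abort("`mass_pg` must be non-negative")
  d_cm <- particle$diameter_nm * 1e-7
  rho <- particle$density_g_cm3               # g/cm^3
  mass_g <- mass_pg * 1e-12
  per_particle_g <- rho * pi * d_cm^3 / 6
  tibble(mass_pg = mass_pg,
         number = mass_g / per_particle_g,
         surface_area_cm2 = mass_g * 6 / (rho * d_cm))
}

#' Hatch-Choate count-to-mass median diameter conversion
#'
#' For a single lognormal mode, the mass (volume) median diameter follows
#' from the count median diameter as `MMD = CMD * exp(3 * ln(GSD)^2)`.
#' Multimodal spectra are out of scope: the relation holds for one mode only.
#'
#' @param dist an [aerosol_distribution()]
#' @return mass median diameter (nm)
#' @examples
#' cmd_to_mmd(spio_aerosol())  # about 146 nm
#' @export
cmd_to_mmd <- function(dist) {
  stopifnot(inherits(dist, "aerosol_distribution"))
  with_unit(dist$cmd_nm * exp(3 * log(dist$gsd)^2), "nm")
}

#' Inverse Hatch-Choate conversion
#'
#' @param mmd_nm mass median diameter (nm)
#' @param gsd geometric standard deviation (>= 1)
#' @return count median diameter (nm)
#' @export
mmd_to_cmd <- function(mmd_nm, gsd) {
  .check_positive(mmd_nm, "mmd_nm")
  if (gsd < 1) abort("`gsd` must be >= 1")
  with_unit(mmd_nm / exp(3 * log(gsd)^2), "nm")
}
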