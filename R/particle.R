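#' Physical description of a copper particle species
#'
#' A `particle_spec` records the geometry and composition the shrinking core
#' model needs: the initial particle radius \eqn{R}, the particle density
#' \eqn{\rho_{NP}}, and the copper mass fraction \eqn{w_{Cu}} that converts
#' compound mass (e.g. CuO) to released copper mass. Particles are assumed
#' homogeneous spheres of common radius.
#'
#' @param species_label character label, e.g. `"Cu-NPs"`.
#' @param radius_m initial particle radius \eqn{R} in metres (> 0).
#' @param density_kg_m3 particle density \eqn{\rho_{NP}} in kg/m\eqn{^3} (> 0).
#' @param copper_mass_fraction mass fraction of copper in the compound,
#'   in (0, 1]; 1 for elemental Cu, 63.546/79.545 for CuO.
#' @return an object of class `particle_spec`.
#' @examples
#' particle_spec("Cu-NPs", radius_m = 12.5e-9, density_kg_m3 = 8960)
#' @export
particle_spec <- function(species_label, radius_m, density_kg_m3,
                          copper_mass_fraction = 1) {
  if (!is.character(species_label) || length(species_label) != 1L)
    stop_input("'species_label' must be a single string")
  check_number(radius_m, "radius_m", positive = TRUE)
  check_number(density_kg_m3, "density_kg_m3", positive = TRUE)
  check_number(copper_mass_fraction, "copper_mass_fraction")
  if (copper_mass_fraction <= 0 || copper_mass_fraction > 1)
    stop_input("'copper_mass_fraction' must be in (0, 1]")
  structure(
    list(species_label = species_label,
         radius_m = radius_m,
         density_kg_m3 = density_kg_m3,
         copper_mass_fraction = copper_mass_fraction),
    class = "particle_spec"
  )
}

#' @rdname particle_spec
#' @details `particle_spec_cu()` and `particle_spec_cuo()` are presets for the
#' commercial nanoparticles of the dissolution protocol: supplier size bounds
#' of < 25 nm (Cu) and < 50 nm (CuO) are diameters, so the default radii are
#' 12.5 nm and 25 nm; densities are handbook values (Cu 8960, CuO 6315
#' kg/m\eqn{^3}). All are overridable.
#' @export
particle_spec_cu <- function(radius_m = 12.5e-9, density_kg_m3 = 8960) {
  particle_spec("Cu-NPs", radius_m, density_kg_m3, copper_mass_fraction = 1)
}

#' @rdname particle_spec
#' @export
particle_spec_cuo <- function(radius_m = 25e-9, density_kg_m3 = 6315) {
  particle_spec("CuO-NPs", radius_m, density_kg_m3,
                copper_mass_fraction = 63.546 / 79.545)
}

#' @export
print.particle_spec <- function(x, ...) {
  cat(sprintf("<particle_spec> %s: R = %.3g nm, rho = %g kg/m3, w_Cu = %.4g\n",
              x$species_label, x$radius_m * 1e9, x$density_kg_m3,
              x$copper_mass_fraction))
  invisible(x)
}

#' Mass of a single particle
#'
#' \eqn{m_p = \rho_{NP} \frac{4}{3}\pi R^3}, in kg.
#'
#' @param spec a [particle_spec()].
#' @return single-particle mass in kg.
#' @export
particle_mass <- function(spec) {
  stopifnot(inherits(spec, "particle_spec"))
  spec$density_kg_m3 * (4 / 3) * pi * spec$radius_m^3
}

#' Particle count implied by a total compound mass
#'
#' The geometric particle number \eqn{N = m / (\rho_{NP}\frac{4}{3}\pi R^3)}
#' expected from the loaded mass and the nominal particle size. Fitted
#' apparent particle numbers \eqn{N_0} fall well below this count when
#' particles agglomerate in suspension.
#'
#' @param total_compound_mass_kg total mass of the particle compound in kg.
#' @param spec a [particle_spec()].
#' @return expected particle count (dimensionless).
#' @export
particle_count_from_mass <- function(total_compound_mass_kg, spec) {
  check_number(total_compound_mass_kg, "total_compound_mass_kg", positive = TRUE)
  total_compound_mass_kg / particle_mass(spec)
}
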