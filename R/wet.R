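#' Proton stopping power and water-equivalent thickness
#'
#' Mass stopping powers are computed from the Bethe formula with compound
#' mean excitation energies and `Z/A` values from the standard reference
#' tables (as tabulated by NIST): water `Z/A = 0.55509`, `I = 75.0` eV;
#' polycarbonate `Z/A = 0.52697`, `I = 73.1` eV, density 1.20 g/cm3;
#' PMMA `Z/A = 0.53937`, `I = 74.0` eV, density 1.19 g/cm3.
#'
#' The water-equivalent thickness (WET) of a slab is its physical thickness
#' times the ratio of linear stopping powers (material over water) at the
#' given proton energy.
#'
#' @name wet
NULL

# compound data: Z/A, mean excitation energy I (eV), density (g/cm3)
.materials <- list(
  water         = list(za = 0.55509, i_ev = 75.0, density = 1.000),
  polycarbonate = list(za = 0.52697, i_ev = 73.1, density = 1.200),
  pmma          = list(za = 0.53937, i_ev = 74.0, density = 1.190)
)

#' Bethe mass stopping power for protons
#'
#' @param energy_MeV Proton kinetic energy in MeV.
#' @param za Ratio `Z/A` of the medium.
#' @param i_ev Mean excitation energy in eV.
#' @return Mass stopping power in MeV cm2/g.
#' @export
bethe_mass_stopping_power <- function(energy_MeV, za, i_ev) {
  if (energy_MeV <= 0) stop("`energy_MeV` must be > 0", call. = FALSE)
  K <- 0.307075          # MeV cm2 / mol
  me <- 0.5109989        # electron mass, MeV
  mp <- 938.27209        # proton mass, MeV
  gamma <- 1 + energy_MeV / mp
  beta2 <- 1 - 1 / gamma^2
  tmax <- 2 * me * beta2 * gamma^2 /
    (1 + 2 * gamma * me / mp + (me / mp)^2)
  i_mev <- i_ev * 1e-6
  K * za / beta2 *
    (0.5 * log(2 * me * beta2 * gamma^2 * tmax / i_mev^2) - beta2)
}

#' Linear stopping-power ratio of a material to water
#' @param material One of `"water"`, `"polycarbonate"`, `"pmma"`.
#' @param energy_MeV Proton kinetic energy in MeV.
#' @return Dimensionless linear stopping-power ratio.
#' @export
stopping_power_ratio <- function(material, energy_MeV) {
  m <- .materials[[tolower(material)]]
  if (is.null(m)) {
    stop(sprintf("unknown material '%s' (have: %s)", material,
                 paste(names(.materials), collapse = ", ")), call. = FALSE)
  }
  w <- .materials$water
  sp_m <- bethe_mass_stopping_power(energy_MeV, m$za, m$i_ev) * m$density
  sp_w <- bethe_mass_stopping_power(energy_MeV, w$za, w$i_ev) * w$density
  sp_m / sp_w
}

#' Water-equivalent thickness of a slab
#'
#' @param thickness_mm Physical slab thickness in mm.
#' @param material Material name (see [stopping_power_ratio()]).
#' @param energy_MeV Proton kinetic energy in MeV.
#' @return WET in mm.
#' @examples
#' wet_of_slab(46.51, "polycarbonate", 90)  # ~53.16 mm
#' @export
wet_of_slab <- function(thickness_mm, material, energy_MeV) {
  if (thickness_mm < 0) stop("`thickness_mm` must be >= 0", call. = FALSE)
  thickness_mm * stopping_power_ratio(material, energy_MeV)
}
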