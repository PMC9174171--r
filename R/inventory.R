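#' Planetary phosphorus inventory from chondritic abundance
#'
#' First-order estimate of a rocky planet's total P endowment: the CI
#' chondritic P mass fraction scaled to the planet mass. With the 1,080 ppm
#' CI abundance and Earth's mass this gives ~6.45e21 kg.
#'
#' @param ppm Chondritic P abundance, parts per million by mass
#'   (default 1080).
#' @param planet_mass Planet mass, kg (default Earth, 5.97e24).
#' @return Total planetary P inventory, kg.
#' @examples
#' chondritic_inventory() # ~6.45e21 kg
#' @export
chondritic_inventory <- function(ppm = 1080, planet_mass = 5.97e24) {
  ppm * 1e-6 * planet_mass
}

#' Core / bulk-silicate partition of the planetary P inventory
#'
#' Splits a total inventory by the core sequestration fraction. For Earth's
#' rapid core formation ~90% of the initial P ends up in the core
#' (~5.8e21 kg, ~0.3% of the core's mass), leaving a ~6.5e20 kg residual
#' available to the bulk silicate Earth.
#'
#' @param inventory Total planetary P, kg (default [chondritic_inventory()]).
#' @param core_fraction Fraction sequestered in the core (default 0.90).
#' @param core_mass Core mass, kg, used to express the core P share as a
#'   mass fraction (default 2.0e24).
#' @return A list with `core_kg`, `residual_kg` (the BSE share) and
#'   `core_mass_fraction`.
#' @examples
#' core_partition()$residual_kg # ~6.5e20 kg
#' @export
core_partition <- function(inventory = chondritic_inventory(),
                           core_fraction = 0.90, core_mass = 2.0e24) {
  core <- core_fraction * inventory
  list(
    core_kg = core,
    residual_kg = inventory - core,
    core_mass_fraction = core / core_mass
  )
}

#' Estimated modern terrestrial phosphorus reservoirs
#'
#' The reservoir-by-reservoir modern P contents and rock masses used to
#' parameterize and evaluate the model, as a tidy tibble.
#'
#' @param structure A [p_structure()].
#' @return Tibble with columns `reservoir`, `modern_p_kg`, `rock_mass_kg`.
#' @export
modern_reservoirs <- function(structure = p_structure()) {
  tibble::tibble(
    reservoir = RESERVOIRS,
    modern_p_kg = unname(structure$modern_p),
    rock_mass_kg = unname(structure$rock_masses)
  )
}

#' Total non-core (bulk silicate Earth) modern phosphorus
#'
#' Sum of the modern P contents of the seven BSE reservoirs — the basis for
#' the 8.4e20 kg starting seed of the main model.
#'
#' @param structure A [p_structure()].
#' @return Mass, kg.
#' @export
bse_modern_total <- function(structure = p_structure()) {
  sum(structure$modern_p[setdiff(RESERVOIRS, "CORE")])
}

#' Total flux from an areal rate
#'
#' `rate_per_km2 * area_km2`: turns an area-averaged flux calibration into a
#' global total, e.g. the modern aeolian calibration
#' (27 kg P km^-2 yr^-1 over 1.48e8 km^2 of land gives 4.0e9 kg yr^-1) or
#' the literature riverine calibration (2.8e4 kg P km^-2 yr^-1 giving
#' ~4.1e12 kg yr^-1).
#'
#' @param rate_per_km2 Areal rate, kg km^-2 yr^-1.
#' @param area_km2 Area, km^2.
#' @return Total flux, kg yr^-1.
#' @export
areal_flux_total <- function(rate_per_km2, area_km2) {
  rate_per_km2 * area_km2
}
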