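#' Substitution-credit parameters
#'
#' Constants for the two Scope 4 substitution pathways: wood fuel
#' displacing natural-gas energy, and construction sawnwood displacing a
#' single-skin 140-mm concrete-block-and-mortar wall (10:3 sand:cement,
#' 10-mm jointing). The wall emission factor is a single per-m2 constant
#' composed offline from block, sand and cement factors so the credit
#' stays auditable while the underlying factors remain inputs.
#'
#' @param timber_per_wall m3 of timber per m2 of timber-framed wall
#'   (industry-standard design value 0.0175).
#' @param timber_density_20mc Timber density at 20 percent moisture
#'   content, kg/m3.
#' @param concrete_wall_ef kg CO2e per m2 of the displaced concrete wall.
#' @param gas_ef kg CO2e per MJ of delivered natural-gas energy.
#' @param wood_energy_yield MJ delivered per tonne of wood fuel (green).
#' @param energy_sector,minerals_sector Decarbonisation sectors applied to
#'   the gas and concrete factors respectively.
#' @return A `substitution_spec` list.
#' @export
substitution_spec <- function(timber_per_wall = 0.0175,
                              timber_density_20mc = 500,
                              concrete_wall_ef = 10,
                              gas_ef = 0.066,
                              wood_energy_yield = 9000,
                              energy_sector = "gas_energy",
                              minerals_sector = "minerals") {
  vals <- c(timber_per_wall, timber_density_20mc, concrete_wall_ef,
            gas_ef, wood_energy_yield)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all substitution parameters must be positive", call. = FALSE)
  }
  structure(list(timber_per_wall = timber_per_wall,
                 timber_density_20mc = timber_density_20mc,
                 concrete_wall_ef = concrete_wall_ef,
                 gas_ef = gas_ef,
                 wood_energy_yield = wood_energy_yield,
                 energy_sector = energy_sector,
                 minerals_sector = minerals_sector),
            class = "substitution_spec")
}

#' Avoided fossil-fuel emissions from wood energy
#'
#' `credit = -wood_fuel x wood_energy_yield x gas_ef x decarbonisation
#' multiplier` for the energy sector: as the counterfactual energy system
#' decarbonises, the credit shrinks, reaching zero under a fully
#' decarbonised grid. Biogenic CO2 from the wood itself is not added here;
#' it is released through the HWP pool (fuelwood is immediate release),
#' avoiding double counting.
#'
#' @param wood_fuel Wood fuel burned, tonnes/yr (>= 0).
#' @param spec A [substitution_spec()].
#' @param year Calendar year.
#' @param schedule A [decarb_schedule()] containing the energy sector.
#' @return Credit in t CO2e/yr (<= 0).
#' @export
#' @examples
#' sch <- decarb_schedule(data.frame(sector = "gas_energy",
#'                                   step_year = 2030, multiplier = 0.5))
#' fuel_substitution_credit(10, substitution_spec(gas_ef = 0.06,
#'   wood_energy_yield = 10000), 2025, sch)
fuel_substitution_credit <- function(wood_fuel, spec, year, schedule) {
  if (wood_fuel < 0) stop("wood_fuel must be non-negative", call. = FALSE)
  m <- decarb_multiplier(spec$energy_sector, year, schedule)
  -wood_fuel * spec$wood_energy_yield * spec$gas_ef * m / 1000
}

#' Avoided concrete-wall emissions from construction timber
#'
#' The mass of construction timber (at 20 percent moisture) is translated
#' into an area of timber-framed wall (`mass / density / timber_per_wall`)
#' and each m2 of timber wall displaces one m2 of concrete-block wall.
#' Manufacturing emissions of the timber wall itself sit in the Scope 1-3
#' process inventory, not inside this credit.
#'
#' @param sawnwood_mass Construction timber, tonnes at 20 percent
#'   moisture per year (>= 0).
#' @param spec A [substitution_spec()].
#' @param year Calendar year.
#' @param schedule A [decarb_schedule()] containing the minerals sector.
#' @return Credit in t CO2e/yr (<= 0).
#' @export
construction_substitution_credit <- function(sawnwood_mass, spec, year,
                                             schedule) {
  if (sawnwood_mass < 0) stop("sawnwood_mass must be non-negative", call. = FALSE)
  if (spec$timber_density_20mc <= 0) stop("zero timber density", call. = FALSE)
  m <- decarb_multiplier(spec$minerals_sector, year, schedule)
  wall_m2 <- (sawnwood_mass * 1000 / spec$timber_density_20mc) /
    spec$timber_per_wall
  -wall_m2 * spec$concrete_wall_ef * m / 1000
}

#' Convert green tonnes to tonnes at 20 percent moisture content
#'
#' @param gt Green tonnes.
#' @param convention A [carbon_convention()].
#' @return Tonnes at 20 percent moisture.
#' @export
green_tonnes_to_20mc <- function(gt, convention = carbon_convention()) {
  gt * (1 - convention$moisture_green) / 0.8
}
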