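# Predator energetics calculator: from a daily energy requirement through a
# fat:protein intake split, population-level annual fat demand, prey biomass
# required at a given diet fraction and prey lipid content, and the fraction
# of a regional prey biomass this represents.  All steps are linear, so each
# is exposed separately and composes cleanly.

.check_pos <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    if (!is.numeric(vals[[nm]]) || any(vals[[nm]] <= 0)) {
      stop(nm, " must be positive")
    }
  }
}

#' Daily fat and protein intake mass from an energy requirement
#'
#' @param daily_kcal energy requirement, kcal per bear per day.
#' @param fat_fraction proportion of energy supplied by fat, in [0, 1].
#' @param kcal_per_g_fat energy density of fat (default 9 kcal/g).
#' @param kcal_per_g_protein energy density of protein (default 4 kcal/g).
#' @return named vector: `fat_kg_day`, `protein_kg_day`.
#' @export
daily_intake_mass <- function(daily_kcal, fat_fraction = 0.8,
                              kcal_per_g_fat = 9, kcal_per_g_protein = 4) {
  .check_pos(daily_kcal = daily_kcal, kcal_per_g_fat = kcal_per_g_fat,
             kcal_per_g_protein = kcal_per_g_protein)
  if (fat_fraction < 0 || fat_fraction > 1) {
    stop("fat_fraction must lie in [0, 1]")
  }
  c(fat_kg_day = fat_fraction * daily_kcal / kcal_per_g_fat / 1000,
    protein_kg_day = (1 - fat_fraction) * daily_kcal /
      kcal_per_g_protein / 1000)
}

#' Population-level annual fat consumption
#'
#' @param kg_fat_per_bear_day per-bear daily fat intake, kg.
#' @param n_bears subpopulation size.
#' @param days_per_year default 365.
#' @return thousand kg fat per year.
#' @export
population_annual_fat <- function(kg_fat_per_bear_day, n_bears,
                                  days_per_year = 365) {
  .check_pos(kg_fat_per_bear_day = kg_fat_per_bear_day)
  if (n_bears < 0) stop("n_bears must be nonnegative")
  kg_fat_per_bear_day * n_bears * days_per_year / 1000
}

#' Prey biomass required to supply an annual fat demand
#'
#' @param annual_fat_thousand_kg total annual fat, thousand kg.
#' @param diet_fraction proportion of the diet made up of the focal prey.
#' @param prey_lipid_fraction lipid proportion of the prey as consumed.
#' @return thousand kg prey per year.
#' @export
prey_biomass_required <- function(annual_fat_thousand_kg, diet_fraction,
                                  prey_lipid_fraction) {
  .check_pos(annual_fat_thousand_kg = annual_fat_thousand_kg,
             diet_fraction = diet_fraction,
             prey_lipid_fraction = prey_lipid_fraction)
  if (diet_fraction > 1 || prey_lipid_fraction > 1) {
    stop("fractions must lie in (0, 1]")
  }
  annual_fat_thousand_kg * diet_fraction / prey_lipid_fraction
}

#' Regional prey biomass from density and area
#'
#' @param density biomass density, kg per km^2.
#' @param area region area, km^2.
#' @return kg.
#' @export
regional_biomass <- function(density, area) {
  .check_pos(density = density, area = area)
  density * area
}

#' Consumed biomass as a percentage of the regional biomass
#'
#' @param consumed_kg annual consumption, kg.
#' @param regional_kg regional standing biomass, kg.
#' @return percent.
#' @export
fraction_of_regional <- function(consumed_kg, regional_kg) {
  .check_pos(consumed_kg = consumed_kg, regional_kg = regional_kg)
  100 * consumed_kg / regional_kg
}

#' Full energetics chain
#'
#' Composes the individual steps and returns every intermediate, both
#' unrounded and display-rounded, so rounding conventions stay transparent.
#'
#' @inheritParams daily_intake_mass
#' @param n_bears subpopulation size.
#' @param diet_fraction proportion of the diet from the focal prey.
#' @param prey_lipid_fraction lipid proportion of the focal prey.
#' @param density,area regional prey biomass density (kg/km^2) and area (km^2).
#' @param days_per_year default 365.
#' @param intake_rounding decimal places the per-bear daily fat intake is
#'   truncated to before population scaling (the "for simplicity" convention
#'   of back-of-envelope consumption arithmetic: 1.07 kg/day is carried
#'   forward as 1.0).  NULL propagates the unrounded value.
#' @return data.frame of class `energetics_chain`: one row per quantity with
#'   `value` (unrounded within each step), `display` (rounded as
#'   conventionally printed) and `unit`.
#' @export
energetics_chain <- function(daily_kcal = 12000, fat_fraction = 0.8,
                             kcal_per_g_fat = 9, kcal_per_g_protein = 4,
                             n_bears = 900, diet_fraction = 0.17,
                             prey_lipid_fraction = 0.10,
                             density = 280, area = 50000,
                             days_per_year = 365, intake_rounding = 1) {
  all_fat <- daily_intake_mass(daily_kcal, 1, kcal_per_g_fat,
                               kcal_per_g_protein)
  all_protein <- daily_intake_mass(daily_kcal, 0, kcal_per_g_fat,
                                   kcal_per_g_protein)
  mixed <- daily_intake_mass(daily_kcal, fat_fraction, kcal_per_g_fat,
                             kcal_per_g_protein)
  fat_carried <- if (is.null(intake_rounding)) mixed[["fat_kg_day"]] else
    floor(mixed[["fat_kg_day"]] * 10^intake_rounding) / 10^intake_rounding
  annual_fat <- population_annual_fat(fat_carried, n_bears, days_per_year)
  annual_prey_fat <- annual_fat * diet_fraction
  prey_mass <- prey_biomass_required(annual_fat, diet_fraction,
                                     prey_lipid_fraction)
  regional <- regional_biomass(density, area)
  pct <- fraction_of_regional(prey_mass * 1000, regional)
  out <- data.frame(
    quantity = c("fat_only_intake", "protein_only_intake",
                 "mixed_fat_intake", "mixed_protein_intake",
                 "population_annual_fat", "prey_annual_fat",
                 "prey_biomass_required", "regional_biomass",
                 "percent_of_regional"),
    value = c(all_fat[["fat_kg_day"]], all_protein[["protein_kg_day"]],
              mixed[["fat_kg_day"]], mixed[["protein_kg_day"]],
              annual_fat, annual_prey_fat, prey_mass, regional, pct),
    display = c(round(all_fat[["fat_kg_day"]], 1),
                round(all_protein[["protein_kg_day"]], 1),
                round(mixed[["fat_kg_day"]], 1),
                round(mixed[["protein_kg_day"]], 1),
                round(annual_fat), round(annual_prey_fat),
                round(prey_mass), round(regional), round(pct)),
    unit = c("kg fat/bear/day", "kg protein/bear/day", "kg fat/bear/day",
             "kg protein/bear/day", "thousand kg fat/yr",
             "thousand kg fat/yr", "thousand kg prey/yr", "kg", "%"))
  class(out) <- c("energetics_chain", "data.frame")
  out
}

#' @export
print.energetics_chain <- function(x, ...) {
  cat("Energetics chain:\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-22s %12.4g  (~%s %s)\n", x$quantity[i], x$value[i],
                format(x$display[i], big.mark = ","), x$unit[i]))
  }
  invisible(x)
}
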