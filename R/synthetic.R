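# Synthetic-data generator.
#
# Emulates the study structure the analysis assumes: a 5-species Arctic prey
# library (ringed seal, bearded seal, beluga whale, bowhead whale, seabird
# eggs/nestlings), predator cohorts across four sex/age classes (AF, AM, SF,
# SM) and 13 capture years, multiplicative calibration distortion, and
# annual sea-ice indices trending with year.  Signature noise is
# logistic-normal (additive Gaussian on the log scale, closed by softmax) so
# covariance among fatty acids could be injected; diets are Dirichlet.

DEFAULT_SPECIES <- c("ringed_seal", "bearded_seal", "beluga",
                     "bowhead", "seabird")

#' Define a synthetic scenario
#'
#' A scenario bundles every generator parameter; the defaults mirror the
#' study design: 5 prey species with specimen counts (89, 20, 29, 64, 23),
#' ~20 fatty acids, 4 sex/age classes over capture years 2004-2016, about
#' 500 predators, baseline diet centered on ringed seal with class-specific
#' tilts (adult males lower ringed seal, higher bowhead).
#'
#' @param seed root seed; all generator randomness flows from it through
#'   named substreams.
#' @param n_fatty_acids number of fatty acids.
#' @param species species labels.
#' @param n_specimens per-species specimen counts.
#' @param lipid per-species lipid fractions (marine mammals 1.0 =
#'   blubber-only feeding assumption; seabird 0.10 = whole-homogenate lipid).
#' @param dispersion within-species signature dispersion, SD on the log
#'   scale of the logistic-normal.
#' @param separation mixing weight of each species mean away from the common
#'   mean: 1 = fully separated, 0 = identical species.
#' @param cc_spread log-scale SD of the calibration coefficients around 1.
#' @param diet_mean baseline biomass diet proportions (library species
#'   order).
#' @param diet_concentration Dirichlet concentration for per-bear diets
#'   (higher = less between-bear variation).
#' @param class_tilt named list of per-class multiplicative tilts applied to
#'   `diet_mean` (re-closed); defaults encode the adult-male shift away from
#'   ringed seal toward bowhead.
#' @param year_effect_sd SD of log-scale annual tilts shared by all bears of
#'   a year (interannual diet variation).
#' @param predator_noise_sd logistic-normal SD of predator signature noise;
#'   the default is the within-species dispersion attenuated by the
#'   effective number of prey consumed (0.35 / sqrt(30) ~ 0.06), since an
#'   adipose signature integrates many feeding events.
#' @param years capture years.
#' @param class_probs sampling probabilities of the four classes.
#' @param n_predators cohort size.
#' @param ice_base,ice_trend,ice_noise_sd ice-free-day generator: baseline
#'   days in the first year, additional days per year, and annual noise SD.
#' @return list of class `fas_scenario`.
#' @export
synthetic_scenario <- function(seed = 1L,
                               n_fatty_acids = 20L,
                               species = DEFAULT_SPECIES,
                               n_specimens = c(89L, 20L, 29L, 64L, 23L),
                               lipid = c(1, 1, 1, 1, 0.10),
                               dispersion = 0.35,
                               separation = 1,
                               cc_spread = 0.3,
                               diet_mean = c(0.464, 0.196, 0.02,
                                             0.15, 0.17),
                               diet_concentration = 30,
                               class_tilt = list(AM = c(0.75, 1, 1, 1.6, 1),
                                                 SM = c(0.85, 1, 1, 1.1, 1)),
                               year_effect_sd = 0.15,
                               predator_noise_sd = 0.06,
                               years = 2004:2016,
                               class_probs = c(AF = 0.3, AM = 0.3,
                                               SF = 0.2, SM = 0.2),
                               n_predators = 125L,
                               ice_base = 90, ice_trend = 3,
                               ice_noise_sd = 10) {
  stopifnot(length(species) == length(n_specimens),
            length(species) == length(lipid),
            length(species) == length(diet_mean),
            all(n_specimens >= 2L), n_fatty_acids >= 2L,
            dispersion >= 0, cc_spread >= 0, predator_noise_sd >= 0,
            diet_concentration > 0, separation >= 0, separation <= 1,
            all(diet_mean > 0))
  diet_mean <- diet_mean / sum(diet_mean)
  # species mean signatures: seeded Dirichlet profiles, pulled toward the
  # common mean by (1 - separation)
  base <- .with_subseed(seed, "species_means", {
    m <- matrix(stats::rgamma(length(species) * n_fatty_acids,
                              shape = 0.8), length(species))
    m / rowSums(m)
  })
  common <- colMeans(base)
  means <- separation * base +
    (1 - separation) * matrix(common, length(species), n_fatty_acids,
                              byrow = TRUE)
  means <- means / rowSums(means)
  fa <- sprintf("FA%02d", seq_len(n_fatty_acids))
  colnames(means) <- fa
  rownames(means) <- species
  structure(list(seed = seed, species = species, fa = fa,
                 n_specimens = stats::setNames(n_specimens, species),
                 lipid = stats::setNames(lipid, species),
                 species_means = means, dispersion = dispersion,
                 cc_spread = cc_spread,
                 diet_mean = stats::setNames(diet_mean, species),
                 diet_concentration = diet_concentration,
                 class_tilt = class_tilt,
                 year_effect_sd = year_effect_sd,
                 predator_noise_sd = predator_noise_sd,
                 years = years, class_probs = class_probs,
                 n_predators = n_predators,
                 ice_base = ice_base, ice_trend = ice_trend,
                 ice_noise_sd = ice_noise_sd),
            class = "fas_scenario")
}

# logistic-normal draw around a simplex mean: softmax(log(mu) + N(0, sd))
.rlogistic_normal <- function(n, mu, sd) {
  lm_ <- log(mu)
  t(vapply(seq_len(n), function(i) {
    z <- lm_ + stats::rnorm(length(mu), sd = sd)
    z <- z - max(z)
    e <- exp(z)
    e / sum(e)
  }, numeric(length(mu))))
}

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g <- alpha   # pathological underflow guard
  g / sum(g)
}

#' Generate a prey library from a scenario
#'
#' Per species, specimens are drawn from a logistic-normal on the simplex
#' centered at the species mean with the scenario's dispersion.
#'
#' @param scenario a [synthetic_scenario()].
#' @return a [prey_library()].
#' @export
gen_prey_library <- function(scenario) {
  sigs <- .with_subseed(scenario$seed, "library", {
    out <- lapply(scenario$species, function(k) {
      m <- .rlogistic_normal(scenario$n_specimens[[k]],
                             scenario$species_means[k, ],
                             scenario$dispersion)
      colnames(m) <- scenario$fa
      m
    })
    names(out) <- scenario$species
    out
  })
  prey_library(sigs, lipid = scenario$lipid)
}

#' Generate calibration coefficients
#'
#' Drawn log-normally around 1 with the given spread; strictly positive.
#' Stands in for feeding-trial coefficients, which are an input file in
#' real analyses.
#'
#' @param n_fatty_acids number of fatty acids (or a character vector of
#'   labels).
#' @param spread log-scale SD; 0 gives all-1 coefficients.
#' @param seed integer seed.
#' @return named positive numeric vector.
#' @export
gen_calibration <- function(n_fatty_acids, spread = 0.3, seed = 1L) {
  stopifnot(spread >= 0)
  fa <- if (is.character(n_fatty_acids)) n_fatty_acids else
    sprintf("FA%02d", seq_len(n_fatty_acids))
  cc <- .with_subseed(seed, "cc", exp(stats::rnorm(length(fa), sd = spread)))
  stats::setNames(cc, fa)
}

#' Generate a predator cohort, its true diets, and an ice-index table
#'
#' Per bear: sex/age class and capture year are sampled from the scenario's
#' proportions; the true biomass diet is drawn from a Dirichlet centered on
#' the class-tilted, year-tilted baseline; the predator signature is the
#' fat-weighted prey-mean mixture, inverse-calibration distorted, with
#' logistic-normal noise.  Ice indices follow a linear trend in year plus
#' noise.
#'
#' @param scenario a [synthetic_scenario()].
#' @param lib a [prey_library()] from the same scenario.
#' @param cc calibration coefficients aligned to the scenario's fatty acids.
#' @return list: `predators` ([predator_set()]), `true_diet` (matrix of
#'   biomass proportions, one row per bear), `ice` (`ice_index_table`).
#' @export
gen_predator_cohort <- function(scenario, lib, cc) {
  if (!identical(lib$fa, scenario$fa)) {
    stop("library fatty acids do not match the scenario")
  }
  sp <- scenario$species
  k <- length(sp)
  means <- prey_means(lib)
  n <- scenario$n_predators
  cohort <- .with_subseed(scenario$seed, "cohort", {
    classes <- sample(names(scenario$class_probs), n, replace = TRUE,
                      prob = scenario$class_probs)
    years <- sample(scenario$years, n, replace = TRUE)
    year_tilt <- matrix(stats::rnorm(length(scenario$years) * k,
                                     sd = scenario$year_effect_sd),
                        length(scenario$years), k,
                        dimnames = list(scenario$years, sp))
    true_diet <- matrix(0, n, k, dimnames = list(NULL, sp))
    sig <- matrix(0, n, length(scenario$fa),
                  dimnames = list(NULL, scenario$fa))
    for (i in seq_len(n)) {
      mu <- scenario$diet_mean
      tilt <- scenario$class_tilt[[classes[i]]]
      if (!is.null(tilt)) mu <- mu * tilt
      mu <- mu * exp(year_tilt[as.character(years[i]), ])
      mu <- mu / sum(mu)
      pi_i <- .rdirichlet(scenario$diet_concentration * mu)
      true_diet[i, ] <- pi_i
      alpha <- pi_i * scenario$lipid
      alpha <- alpha / sum(alpha)
      mix <- mixture_signature(alpha, means)
      if (scenario$predator_noise_sd > 0) {
        mix <- drop(.rlogistic_normal(1L, mix, scenario$predator_noise_sd))
      }
      sig[i, ] <- apply_calibration(mix, cc[scenario$fa],
                                    "prey_to_predator")
    }
    list(classes = classes, years = years, true_diet = true_diet,
         sig = sig)
  })
  ice <- .with_subseed(scenario$seed, "ice", {
    yrs <- scenario$years
    t_idx <- seq_along(yrs) - 1L
    clamp <- function(x) pmin(pmax(x, 0), 366)
    data.frame(year = yrs,
               ifd50 = clamp(scenario$ice_base + scenario$ice_trend * t_idx +
                               stats::rnorm(length(yrs),
                                            sd = scenario$ice_noise_sd)),
               ifd15 = clamp(scenario$ice_base * 0.7 +
                               scenario$ice_trend * t_idx +
                               stats::rnorm(length(yrs),
                                            sd = scenario$ice_noise_sd)),
               melt_season = clamp(scenario$ice_base * 1.4 +
                                     scenario$ice_trend * t_idx +
                                     stats::rnorm(length(yrs),
                                                  sd = scenario$ice_noise_sd)))
  })
  class(ice) <- c("ice_index_table", "data.frame")
  info <- data.frame(id = sprintf("bear%03d", seq_len(n)),
                     class = cohort$classes, year = cohort$years)
  list(predators = predator_set(info, cohort$sig),
       true_diet = cohort$true_diet,
       ice = ice)
}
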