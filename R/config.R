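#' Configuration for the synthetic mesocosm generator
#'
#' Bundles every tunable parameter of the synthetic experiment: the factorial
#' design (communities, treatments, replicates, surveys) and the stochastic
#' model for herbivore presence, counts, leaf damage, plant growth and the
#' effect of provenance on each. Defaults reproduce the structure of the
#' motivating mesocosm experiment: 20 communities of 8 plants from a
#' 39-species pool (19 native, 20 exotic), 20 herbivore species (7 native,
#' 13 exotic; 13 deliberately added, 7 self-colonised), 2 herbivore x 2 soil
#' treatments x 2 replicates = 160 mesocosms, 8 survey occasions.
#'
#' Effect-size defaults are taken from the community-level results the design
#' emulates: exotic plants roughly double a herbivore's odds of presence
#' (`exotic_interaction_odds_multiplier = 2`), carry 72% more herbivore
#' biomass per realised interaction (`exotic_biomass_multiplier = 1.72`),
#' and lose 31% of their biomass to herbivory
#' (`herbivory_biomass_penalty_exotic = 0.31`); herbivore exclusion retains
#' 21% of presences (`minus_H_presence_retention = 0.21`, a 79% reduction).
#'
#' @param seed Integer master seed. Per-mesocosm substreams are derived from
#'   it by stable hashing, so subsetting a design does not reshuffle the
#'   remaining mesocosms.
#' @param n_communities Number of unique plant communities (default 20).
#' @param community_size Plant species per community (default 8).
#' @param replicates Replicates per community x treatment cell (default 2).
#' @param herbivore_treatments Character subset of `c("plus_H", "minus_H")`.
#' @param soil_treatments Character subset of `c("home", "away")`.
#' @param n_surveys Number of survey occasions (default 8).
#' @param n_native_plants,n_exotic_plants Plant pool sizes (19 + 20).
#' @param n_woody_native,n_woody_exotic Woody species within each pool.
#' @param n_native_herbivores,n_exotic_herbivores Herbivore pool (7 + 13).
#' @param n_added_herbivores Deliberately added species (13); the rest are
#'   self-colonisers.
#' @param host_range_size Integer range (min, max) of fundamental host-range
#'   sizes drawn per herbivore from the 39-species plant pool.
#' @param presence_base_prob Per (plant, herbivore, survey) probability that
#'   an in-range herbivore is recorded feeding on a native plant in a
#'   +Herbivore mesocosm.
#' @param exotic_interaction_odds_multiplier Multiplier on the presence
#'   *odds* when the plant is exotic (> 0).
#' @param exotic_herbivore_prop_exotic_slope Logit-scale slope by which an
#'   *exotic herbivore's* presence increases with the proportion of exotic
#'   species planted in the community.
#' @param minus_H_presence_retention Fraction of the +Herbivore presence
#'   probability retained in -Herbivore mesocosms (removal as thinning).
#' @param count_mean_native Conditional mean number of individuals per
#'   realised (plant, herbivore, survey) record on native plants.
#' @param exotic_biomass_multiplier Multiplier on that conditional mean for
#'   exotic plants; because counts are drawn from a zero-truncated negative
#'   binomial parameterised by its conditional mean, the exotic:native
#'   biomass ratio per realised interaction equals this value exactly.
#' @param count_size Negative-binomial dispersion (size) of counts.
#' @param herbivore_mass_meanlog,herbivore_mass_sdlog Log-normal parameters
#'   for herbivore mean dry mass (g/individual).
#' @param plant_growth Named list with log-normal total-biomass parameters
#'   per plant provenance: `native_meanlog`, `exotic_meanlog`, `sdlog`.
#' @param aboveground_fraction Mean fraction of total biomass allocated
#'   aboveground.
#' @param herbivory_biomass_penalty_exotic Proportional biomass reduction
#'   applied (on the log scale, hence exactly multiplicative) to exotic
#'   plants in +Herbivore mesocosms.
#' @param herbivory_biomass_penalty_native Same for native plants (default 0:
#'   herbivory had no detectable effect on natives).
#' @param damage_category_probabilities Named list `native`/`exotic`, each a
#'   probability vector over damage categories 0..5 for a +Herbivore survey.
#' @param death_prob Independent per-plant probability of dying before the
#'   final survey (dead plants are surveyed fewer times).
#' @param orthogonality_bound Maximum tolerated absolute correlation between
#'   the planted exotic and woody proportions across communities.
#'
#' @return An object of class `mesocosm_config` (a validated list).
#' @examples
#' cfg <- mesocosm_config(seed = 1)
#' cfg$n_surveys
#' @export
mesocosm_config <- function(seed = 1L,
                            n_communities = 20L,
                            community_size = 8L,
                            replicates = 2L,
                            herbivore_treatments = c("plus_H", "minus_H"),
                            soil_treatments = c("home", "away"),
                            n_surveys = 8L,
                            n_native_plants = 19L,
                            n_exotic_plants = 20L,
                            n_woody_native = 7L,
                            n_woody_exotic = 7L,
                            n_native_herbivores = 7L,
                            n_exotic_herbivores = 13L,
                            n_added_herbivores = 13L,
                            host_range_size = c(6L, 16L),
                            presence_base_prob = 0.12,
                            exotic_interaction_odds_multiplier = 2.0,
                            exotic_herbivore_prop_exotic_slope = 1.0,
                            minus_H_presence_retention = 0.21,
                            count_mean_native = 2.5,
                            exotic_biomass_multiplier = 1.72,
                            count_size = 1.0,
                            herbivore_mass_meanlog = log(0.01),
                            herbivore_mass_sdlog = 0.8,
                            plant_growth = list(native_meanlog = log(3),
                                                exotic_meanlog = log(12),
                                                sdlog = 0.8),
                            aboveground_fraction = 0.6,
                            herbivory_biomass_penalty_exotic = 0.31,
                            herbivory_biomass_penalty_native = 0,
                            damage_category_probabilities = list(
                              native = c(0.70, 0.20, 0.07, 0.02, 0.007, 0.003),
                              exotic = c(0.55, 0.27, 0.12, 0.04, 0.014, 0.006)),
                            death_prob = 0.03,
                            orthogonality_bound = 0.1) {
  cfg <- list(seed = as.integer(seed),
              n_communities = as.integer(n_communities),
              community_size = as.integer(community_size),
              replicates = as.integer(replicates),
              herbivore_treatments = match.arg(herbivore_treatments,
                                               c("plus_H", "minus_H"),
                                               several.ok = TRUE),
              soil_treatments = match.arg(soil_treatments,
                                          c("home", "away"),
                                          several.ok = TRUE),
              n_surveys = as.integer(n_surveys),
              n_native_plants = as.integer(n_native_plants),
              n_exotic_plants = as.integer(n_exotic_plants),
              n_woody_native = as.integer(n_woody_native),
              n_woody_exotic = as.integer(n_woody_exotic),
              n_native_herbivores = as.integer(n_native_herbivores),
              n_exotic_herbivores = as.integer(n_exotic_herbivores),
              n_added_herbivores = as.integer(n_added_herbivores),
              host_range_size = as.integer(host_range_size),
              presence_base_prob = presence_base_prob,
              exotic_interaction_odds_multiplier = exotic_interaction_odds_multiplier,
              exotic_herbivore_prop_exotic_slope = exotic_herbivore_prop_exotic_slope,
              minus_H_presence_retention = minus_H_presence_retention,
              count_mean_native = count_mean_native,
              exotic_biomass_multiplier = exotic_biomass_multiplier,
              count_size = count_size,
              herbivore_mass_meanlog = herbivore_mass_meanlog,
              herbivore_mass_sdlog = herbivore_mass_sdlog,
              plant_growth = plant_growth,
              aboveground_fraction = aboveground_fraction,
              herbivory_biomass_penalty_exotic = herbivory_biomass_penalty_exotic,
              herbivory_biomass_penalty_native = herbivory_biomass_penalty_native,
              damage_category_probabilities = damage_category_probabilities,
              death_prob = death_prob,
              orthogonality_bound = orthogonality_bound)
  validate_mesocosm_config(cfg)
  class(cfg) <- "mesocosm_config"
  cfg
}

#' @keywords internal
#' @noRd
validate_mesocosm_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  probs <- c(cfg$presence_base_prob, cfg$minus_H_presence_retention,
             cfg$death_prob, cfg$herbivory_biomass_penalty_exotic,
             cfg$herbivory_biomass_penalty_native,
             unlist(cfg$damage_category_probabilities))
  chk(all(probs >= 0 & probs <= 1), "all probabilities must lie in [0, 1]")
  chk(cfg$exotic_interaction_odds_multiplier > 0,
      "exotic_interaction_odds_multiplier must be > 0")
  chk(cfg$exotic_biomass_multiplier > 0,
      "exotic_biomass_multiplier must be > 0")
  chk(cfg$count_mean_native > 1,
      "count_mean_native must exceed 1 (counts are zero-truncated)")
  chk(cfg$count_size > 0, "count_size must be > 0")
  chk(cfg$n_surveys >= 1, "n_surveys must be >= 1")
  chk(cfg$community_size >= 1, "community_size must be >= 1")
  chk(cfg$n_added_herbivores <=
        cfg$n_native_herbivores + cfg$n_exotic_herbivores,
      "more added herbivores than the herbivore pool holds")
  chk(cfg$n_woody_native <= cfg$n_native_plants &&
        cfg$n_woody_exotic <= cfg$n_exotic_plants,
      "woody species counts exceed pool sizes")
  chk(all(vapply(cfg$damage_category_probabilities, length, 1L) == 6L),
      "damage_category_probabilities must give 6 weights (categories 0-5)")
  invisible(cfg)
}

#' @export
print.mesocosm_config <- function(x, ...) {
  n_meso <- x$n_communities * length(x$herbivore_treatments) *
    length(x$soil_treatments) * x$replicates
  cat("Mesocosm generator configuration\n")
  cat(sprintf("  %d communities x %d herbivore x %d soil treatments x %d reps = %d mesocosms\n",
              x$n_communities, length(x$herbivore_treatments),
              length(x$soil_treatments), x$replicates, n_meso))
  cat(sprintf("  plant pool %d native + %d exotic; herbivore pool %d native + %d exotic\n",
              x$n_native_plants, x$n_exotic_plants,
              x$n_native_herbivores, x$n_exotic_herbivores))
  cat(sprintf("  %d surveys; seed %d\n", x$n_surveys, x$seed))
  invisible(x)
}
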