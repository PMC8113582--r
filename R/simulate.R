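#' Simulate herbivore surveys on a mesocosm design
#'
#' Produces long-format survey records: for each survey occasion, each plant
#' individual and each herbivore species whose fundamental host range contains
#' the plant's species, a Bernoulli presence draw followed by a
#' zero-truncated negative-binomial count of feeding individuals. Pairs
#' outside the generator's fundamental host ranges are never produced.
#'
#' The presence model on the logit scale is
#' `qlogis(p0) + log(odds_mult) * [plant exotic] + slope * prop_exotic *
#' [herbivore exotic]`; in `-Herbivore` mesocosms the resulting probability is
#' multiplied by `minus_H_presence_retention` (herbivore removal modelled as
#' thinning of all species, matching the near-total but imperfect exclusion
#' achieved by cages and hand removal). Counts, given presence, have
#' conditional mean `count_mean_native`, multiplied by
#' `exotic_biomass_multiplier` on exotic plants.
#'
#' Plants that die (independent Bernoulli per plant) are surveyed fewer than
#' `n_surveys` times; the survival schedule is attached as
#' `attr(, "plant_schedule")` and is re-derived identically by
#' [simulate_damage_and_biomass()].
#'
#' @param design A [generate_design()] result.
#' @param config A [mesocosm_config()]; defaults to the one inside `design`.
#' @return A data frame with columns `mesocosm_id`, `survey_index`,
#'   `plant_id`, `plant_species`, `herbivore_species`, `count` (rows only for
#'   positive counts), with the survival schedule as an attribute.
#' @examples
#' d <- generate_design(mesocosm_config(seed = 1, n_communities = 2,
#'                                      replicates = 1, n_surveys = 2))
#' s <- simulate_surveys(d)
#' head(s)
#' @export
simulate_surveys <- function(design, config = design$config) {
  stopifnot(inherits(design, "mesocosm_design"))
  schedule <- .plant_schedule(design, config)
  sched_n <- setNames(schedule$n_surveys_observed, schedule$plant_id)

  herb <- design$herbivores
  herb_exotic <- setNames(herb$provenance == "exotic", herb$species)

  out <- vector("list", nrow(design$mesocosms))
  for (m in seq_len(nrow(design$mesocosms))) {
    meso <- design$mesocosms[m, ]
    plants_m <- design$plant_individuals[
      design$plant_individuals$mesocosm_id == meso$mesocosm_id, ]
    pairs <- merge(design$host_ranges, plants_m,
                   by.x = "plant_species", by.y = "species")
    if (nrow(pairs) == 0L) next
    grid <- pairs[rep(seq_len(nrow(pairs)), each = config$n_surveys), ]
    grid$survey_index <- rep(seq_len(config$n_surveys), nrow(pairs))
    grid <- grid[grid$survey_index <= sched_n[grid$plant_id], ]
    if (nrow(grid) == 0L) next

    eta <- qlogis(config$presence_base_prob) +
      log(config$exotic_interaction_odds_multiplier) *
      (grid$provenance == "exotic") +
      config$exotic_herbivore_prop_exotic_slope * meso$prop_exotic_planted *
      herb_exotic[grid$herbivore_species]
    p <- plogis(eta)
    if (meso$herbivore_treatment == "minus_H")
      p <- p * config$minus_H_presence_retention

    obs <- .with_seed(.substream_seed(config$seed,
                                      paste0("survey_", meso$mesocosm_id)), {
      present <- runif(nrow(grid)) < p
      g <- grid[present, , drop = FALSE]
      if (nrow(g)) {
        target <- config$count_mean_native *
          ifelse(g$provenance == "exotic",
                 config$exotic_biomass_multiplier, 1)
        g$count <- .rztnb_mean(nrow(g), target, config$count_size)
      }
      g
    })
    if (nrow(obs) == 0L) next
    obs$mesocosm_id <- meso$mesocosm_id
    out[[m]] <- data.frame(mesocosm_id = obs$mesocosm_id,
                           survey_index = obs$survey_index,
                           plant_id = obs$plant_id,
                           plant_species = obs$plant_species,
                           herbivore_species = obs$herbivore_species,
                           count = obs$count,
                           stringsAsFactors = FALSE)
  }
  surveys <- do.call(rbind, c(out, list(.empty_surveys())))
  surveys <- surveys[order(surveys$mesocosm_id, surveys$survey_index,
                           surveys$plant_id, surveys$herbivore_species), ]
  rownames(surveys) <- NULL
  attr(surveys, "plant_schedule") <- schedule
  surveys
}

#' @keywords internal
#' @noRd
.empty_surveys <- function() {
  data.frame(mesocosm_id = character(0), survey_index = integer(0),
             plant_id = character(0), plant_species = character(0),
             herbivore_species = character(0), count = integer(0),
             stringsAsFactors = FALSE)
}

# Survival schedule: independent Bernoulli death per plant; dead plants are
# surveyed an (uniform) strictly smaller number of times. Drawn from its own
# substream so simulate_surveys and simulate_damage_and_biomass agree.

#' @keywords internal
#' @noRd
.plant_schedule <- function(design, config) {
  pl <- design$plant_individuals
  out <- vector("list", nrow(design$mesocosms))
  for (m in seq_len(nrow(design$mesocosms))) {
    id <- design$mesocosms$mesocosm_id[m]
    plants_m <- pl[pl$mesocosm_id == id, ]
    n <- nrow(plants_m)
    sched <- .with_seed(.substream_seed(config$seed, paste0("schedule_", id)), {
      dead <- runif(n) < config$death_prob
      n_obs <- rep(config$n_surveys, n)
      if (any(dead) && config$n_surveys > 1L)
        n_obs[dead] <- sample(seq_len(config$n_surveys - 1L), sum(dead),
                              replace = TRUE)
      data.frame(plant_id = plants_m$plant_id, mesocosm_id = id,
                 alive = !dead, n_surveys_observed = n_obs,
                 stringsAsFactors = FALSE)
    })
    out[[m]] <- sched
  }
  do.call(rbind, out)
}

#' Simulate leaf damage scores and end-of-experiment plant biomass
#'
#' Damage: for every (plant, survey) visit an ordinal category 0--5 is drawn
#' from the provenance-specific probability vector; in `-Herbivore` mesocosms
#' the probability mass of the non-zero categories is thinned by
#' `minus_H_presence_retention` (the remainder moves to category 0).
#'
#' Biomass: alive plants draw a log-normal total biomass whose log-location
#' depends on provenance; exotic plants in `+Herbivore` mesocosms are reduced
#' by `herbivory_biomass_penalty_exotic` (multiplicatively, so the geometric
#' +H:-H biomass ratio equals `1 - penalty` exactly), natives by the
#' (default 0) native penalty. The treatment-level penalty stands in for the
#' net effect of realised herbivory. Dead plants get zero biomass and
#' `alive = FALSE`.
#'
#' @param design A [generate_design()] result.
#' @param surveys Optional survey table from [simulate_surveys()]; only used
#'   to cross-check plant ids. Biomass and damage are driven by the design
#'   (treatment-level herbivory effect), so `NULL` is accepted.
#' @param config A [mesocosm_config()]; defaults to the one inside `design`.
#' @param components Which outputs to generate; dropping `"damage"` skips
#'   the per-survey damage draws (useful for biomass-only replications).
#'   The biomass substream is independent of the damage substream, so the
#'   outcomes are identical either way.
#' @return A list with data frames `damage` (`mesocosm_id`, `survey_index`,
#'   `plant_id`, `category`; `NULL` if not requested) and `outcomes`
#'   (`plant_id`, `mesocosm_id`, `species`, `provenance`, `alive`,
#'   `aboveground_biomass_g`, `belowground_biomass_g`,
#'   `n_surveys_observed`).
#' @examples
#' d <- generate_design(mesocosm_config(seed = 1, n_communities = 2,
#'                                      replicates = 1, n_surveys = 2))
#' db <- simulate_damage_and_biomass(d)
#' head(db$outcomes)
#' @export
simulate_damage_and_biomass <- function(design, surveys = NULL,
                                        config = design$config,
                                        components = c("damage",
                                                       "outcomes")) {
  components <- match.arg(components, several.ok = TRUE)
  stopifnot(inherits(design, "mesocosm_design"))
  if (!is.null(surveys)) {
    unknown <- setdiff(surveys$plant_id, design$plant_individuals$plant_id)
    if (length(unknown))
      stop("surveys reference plant ids absent from the design: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  schedule <- .plant_schedule(design, config)
  sched_n <- setNames(schedule$n_surveys_observed, schedule$plant_id)
  sched_alive <- setNames(schedule$alive, schedule$plant_id)

  damage_out <- vector("list", nrow(design$mesocosms))
  outcome_out <- vector("list", nrow(design$mesocosms))
  for (m in seq_len(nrow(design$mesocosms))) {
    meso <- design$mesocosms[m, ]
    plants_m <- design$plant_individuals[
      design$plant_individuals$mesocosm_id == meso$mesocosm_id, ]
    n <- nrow(plants_m)
    n_obs <- sched_n[plants_m$plant_id]
    is_exotic <- plants_m$provenance == "exotic"
    plus_H <- meso$herbivore_treatment == "plus_H"

    dmg <- if (!("damage" %in% components)) NULL else
      .with_seed(.substream_seed(config$seed,
                                 paste0("damage_", meso$mesocosm_id)), {
      rows <- lapply(seq_len(n), function(i) {
        probs <- config$damage_category_probabilities[[plants_m$provenance[i]]]
        if (!plus_H) {
          probs <- probs * config$minus_H_presence_retention
          probs[1] <- probs[1] + (1 - config$minus_H_presence_retention)
        }
        data.frame(mesocosm_id = meso$mesocosm_id,
                   survey_index = seq_len(n_obs[i]),
                   plant_id = plants_m$plant_id[i],
                   category = sample(0:5, n_obs[i], replace = TRUE,
                                     prob = probs),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })

    outc <- if (!("outcomes" %in% components)) NULL else
      .with_seed(.substream_seed(config$seed,
                                 paste0("biomass_", meso$mesocosm_id)), {
      penalty <- ifelse(is_exotic, config$herbivory_biomass_penalty_exotic,
                        config$herbivory_biomass_penalty_native)
      meanlog <- ifelse(is_exotic, config$plant_growth$exotic_meanlog,
                        config$plant_growth$native_meanlog)
      if (plus_H) meanlog <- meanlog + log(1 - penalty)
      total <- rlnorm(n, meanlog, config$plant_growth$sdlog)
      f <- rbeta(n, config$aboveground_fraction * 20,
                 (1 - config$aboveground_fraction) * 20)
      alive <- sched_alive[plants_m$plant_id]
      total[!alive] <- 0
      data.frame(plant_id = plants_m$plant_id,
                 mesocosm_id = meso$mesocosm_id,
                 species = plants_m$species,
                 provenance = plants_m$provenance,
                 alive = unname(alive),
                 aboveground_biomass_g = total * f,
                 belowground_biomass_g = total * (1 - f),
                 n_surveys_observed = unname(n_obs),
                 stringsAsFactors = FALSE)
    })
    damage_out[[m]] <- dmg
    outcome_out[[m]] <- outc
  }
  damage <- NULL
  if ("damage" %in% components) {
    damage <- do.call(rbind, damage_out)
    damage <- damage[order(damage$mesocosm_id, damage$survey_index,
                           damage$plant_id), ]
    rownames(damage) <- NULL
  }
  outcomes <- NULL
  if ("outcomes" %in% components) {
    outcomes <- do.call(rbind, outcome_out)
    rownames(outcomes) <- NULL
  }
  list(damage = damage, outcomes = outcomes)
}

#' Run the full synthetic experiment
#'
#' Convenience wrapper chaining [generate_design()], [simulate_surveys()] and
#' [simulate_damage_and_biomass()].
#'
#' @param config A [mesocosm_config()].
#' @return An object of class `mesocosm_experiment`: list with `design`,
#'   `surveys`, `damage`, `outcomes`.
#' @examples
#' ex <- simulate_mesocosm_experiment(
#'   mesocosm_config(seed = 1, n_communities = 2, replicates = 1,
#'                   n_surveys = 2))
#' names(ex)
#' @export
simulate_mesocosm_experiment <- function(config = mesocosm_config()) {
  design <- generate_design(config)
  surveys <- simulate_surveys(design, config)
  db <- simulate_damage_and_biomass(design, surveys, config)
  structure(list(design = design, surveys = surveys,
                 damage = db$damage, outcomes = db$outcomes),
            class = "mesocosm_experiment")
}

#' @export
print.mesocosm_experiment <- function(x, ...) {
  cat(sprintf("Synthetic mesocosm experiment: %d mesocosms, %d survey records,\n",
              nrow(x$design$mesocosms), nrow(x$surveys)))
  cat(sprintf("  %d damage scores, %d plant outcomes\n",
              nrow(x$damage), nrow(x$outcomes)))
  invisible(x)
}
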