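# Summary statistics that recover the generator's provenance effects from a
# simulated experiment. These are the estimators used by the parameter
# recovery tests; they only consume pipeline-visible tables (plus the
# generator's ground-truth host ranges, which it echoes for this purpose).

#' Host-range web from a design's ground truth
#'
#' Binary plant-species x herbivore-species matrix of the generator's
#' fundamental host ranges (the simulated truth of which the realised
#' meta-web is a subset).
#'
#' @param design A [generate_design()] result.
#' @return Binary matrix shaped like [build_metaweb()] output.
#' @export
truth_host_web <- function(design) {
  stopifnot(inherits(design, "mesocosm_design"))
  mw <- matrix(0L, nrow = nrow(design$plants),
               ncol = nrow(design$herbivores),
               dimnames = list(sort(design$plants$species),
                               sort(design$herbivores$species)))
  mw[cbind(design$host_ranges$plant_species,
           design$host_ranges$herbivore_species)] <- 1L
  attr(mw, "plant_provenance") <-
    setNames(design$plants$provenance, design$plants$species)[rownames(mw)]
  attr(mw, "herbivore_provenance") <-
    setNames(design$herbivores$provenance,
             design$herbivores$species)[colnames(mw)]
  mw
}

#' Survey-level presence records within a host-range web
#'
#' One row per (mesocosm, survey occasion, plant individual, in-range
#' herbivore) with a logical `presence`, i.e. the zero-filled survey-level
#' analogue of [zero_fill_presence()]. Survey occasions beyond a dead
#' plant's last survey are dropped.
#'
#' @param surveys Survey table (as from [simulate_surveys()]).
#' @param design A [generate_design()] result.
#' @param host_web Binary species web; defaults to the generator truth.
#' @return Long data frame with design covariates (`plant_exotic`,
#'   `herbivore_exotic`, `prop_exotic_planted`, `herbivore_treatment`) and
#'   `presence`.
#' @export
survey_presence_records <- function(surveys, design,
                                    host_web = truth_host_web(design)) {
  cfg <- design$config
  schedule <- attr(surveys, "plant_schedule")
  if (is.null(schedule)) schedule <- .plant_schedule(design, cfg)
  sched_n <- setNames(schedule$n_surveys_observed, schedule$plant_id)

  edges <- which(host_web > 0, arr.ind = TRUE)
  hosts <- data.frame(species = rownames(host_web)[edges[, 1]],
                      herbivore_species = colnames(host_web)[edges[, 2]],
                      stringsAsFactors = FALSE)
  pairs <- merge(design$plant_individuals, hosts, by = "species")
  grid <- pairs[rep(seq_len(nrow(pairs)), each = cfg$n_surveys), ]
  grid$survey_index <- rep(seq_len(cfg$n_surveys), nrow(pairs))
  grid <- grid[grid$survey_index <= sched_n[grid$plant_id], ]

  key <- function(df) paste(df$mesocosm_id, df$survey_index, df$plant_id,
                            df$herbivore_species)
  grid$presence <- key(grid) %in% key(surveys)

  herb_prov <- setNames(design$herbivores$provenance,
                        design$herbivores$species)
  meso <- design$mesocosms
  grid <- merge(grid, meso[, c("mesocosm_id", "herbivore_treatment",
                               "prop_exotic_planted")],
                by = "mesocosm_id", sort = FALSE)
  grid$plant_exotic <- as.integer(grid$provenance == "exotic")
  grid$herbivore_exotic <- as.integer(herb_prov[grid$herbivore_species] ==
                                        "exotic")
  rownames(grid) <- NULL
  grid[, c("mesocosm_id", "survey_index", "plant_id", "species",
           "herbivore_species", "herbivore_treatment",
           "prop_exotic_planted", "plant_exotic", "herbivore_exotic",
           "presence")]
}

#' Recover the generator's provenance effects from simulated data
#'
#' Four estimators matching the generator's data model:
#' \describe{
#'   \item{presence_odds_ratio}{exp of the plant-provenance coefficient of a
#'     logistic regression of survey-level presence (within the host-range
#'     web, +Herbivore mesocosms) on plant provenance plus the exotic
#'     herbivore x planted-exotic-proportion term.}
#'   \item{biomass_ratio}{exp of the plant-provenance coefficient of a
#'     quasi-Poisson log-link regression of per-record herbivore biomass
#'     (count x mean dry mass) on plant provenance and herbivore species --
#'     the exotic:native biomass ratio per realised interaction.}
#'   \item{retention}{ratio of the overall -Herbivore to +Herbivore presence
#'     rates within the host-range web.}
#'   \item{biomass_penalty}{1 minus the geometric-mean ratio of alive exotic
#'     plant biomass in +Herbivore vs -Herbivore mesocosms (log-scale linear
#'     model).}
#' }
#'
#' @param experiment A [simulate_mesocosm_experiment()] result (or a list
#'   with `design`, `surveys`, `outcomes`).
#' @return Named list with the four estimates.
#' @export
estimate_generator_effects <- function(experiment) {
  design <- experiment$design
  surveys <- experiment$surveys
  outcomes <- experiment$outcomes
  herb <- design$herbivores

  pres <- survey_presence_records(surveys, design)
  plus <- pres[pres$herbivore_treatment == "plus_H", ]
  fit <- stats::glm(presence ~ plant_exotic +
                      herbivore_exotic:prop_exotic_planted,
                    family = stats::binomial(), data = plus)
  presence_or <- unname(exp(stats::coef(fit)["plant_exotic"]))

  minus <- pres[pres$herbivore_treatment == "minus_H", ]
  retention <- if (nrow(minus)) mean(minus$presence) / mean(plus$presence)
               else NA_real_

  mass <- setNames(herb$mean_dry_mass_g, herb$species)
  prov_plant <- setNames(design$plant_individuals$provenance,
                         design$plant_individuals$plant_id)
  obs <- surveys[surveys$mesocosm_id %in%
                   design$mesocosms$mesocosm_id[
                     design$mesocosms$herbivore_treatment == "plus_H"], ]
  obs$biomass <- obs$count * mass[obs$herbivore_species]
  obs$plant_exotic <- as.integer(prov_plant[obs$plant_id] == "exotic")
  bfit <- stats::glm(biomass ~ plant_exotic + herbivore_species,
                     family = stats::quasipoisson(), data = obs)
  biomass_ratio <- unname(exp(stats::coef(bfit)["plant_exotic"]))

  exo <- outcomes[outcomes$alive & outcomes$provenance == "exotic", ]
  exo <- merge(exo, design$mesocosms[, c("mesocosm_id",
                                         "herbivore_treatment")],
               by = "mesocosm_id")
  exo$total <- exo$aboveground_biomass_g + exo$belowground_biomass_g
  exo$plus_H <- as.integer(exo$herbivore_treatment == "plus_H")
  pfit <- stats::lm(log(total) ~ plus_H, data = exo)
  penalty <- unname(1 - exp(stats::coef(pfit)["plus_H"]))

  list(presence_odds_ratio = presence_or,
       biomass_ratio = biomass_ratio,
       retention = retention,
       biomass_penalty = penalty)
}
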