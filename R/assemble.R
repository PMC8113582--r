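# Assembly of quantitative plant-herbivore webs from long-format records.

#' Standardise herbivore counts to mean dry biomass per plant
#'
#' For each (plant individual, herbivore species) pair, sums the counts over
#' all surveys, multiplies by the herbivore's mean dry mass per individual,
#' and divides by the number of times the plant was surveyed (plants that
#' died were surveyed fewer times). This is the link strength `alpha` used in
#' the interaction matrices.
#'
#' @param surveys Data frame with `mesocosm_id`, `survey_index`, `plant_id`,
#'   `plant_species`, `herbivore_species`, `count`.
#' @param herbivores Herbivore species table with `species` and
#'   `mean_dry_mass_g`; a species observed in `surveys` but missing a mass
#'   record is a hard error.
#' @param outcomes Plant outcome table with `plant_id` and
#'   `n_surveys_observed` (>= 1).
#' @return Data frame `mesocosm_id`, `plant_id`, `plant_species`,
#'   `herbivore_species`, `biomass_g` with one row per realised pair (zero
#'   pairs omitted; recover them with [zero_fill_presence()]).
#' @examples
#' s <- data.frame(mesocosm_id = "M1", survey_index = 1:3, plant_id = "M1_a",
#'                 plant_species = "a", herbivore_species = "h",
#'                 count = c(2, 3, 5))
#' h <- data.frame(species = "h", mean_dry_mass_g = 0.02)
#' o <- data.frame(plant_id = "M1_a", n_surveys_observed = 8)
#' standardize_herbivore_biomass(s, h, o)$biomass_g  # 10 * 0.02 / 8
#' @export
standardize_herbivore_biomass <- function(surveys, herbivores, outcomes) {
  .assert_columns(surveys, c("mesocosm_id", "plant_id", "plant_species",
                             "herbivore_species", "count"), "surveys")
  .assert_columns(herbivores, c("species", "mean_dry_mass_g"), "herbivores")
  .assert_columns(outcomes, c("plant_id", "n_surveys_observed"), "outcomes")
  if (nrow(surveys) == 0L)
    return(data.frame(mesocosm_id = character(0), plant_id = character(0),
                      plant_species = character(0),
                      herbivore_species = character(0),
                      biomass_g = numeric(0), stringsAsFactors = FALSE))
  missing_mass <- setdiff(surveys$herbivore_species, herbivores$species)
  if (length(missing_mass))
    stop("no mean dry mass recorded for herbivore species: ",
         paste(sort(missing_mass), collapse = ", "), call. = FALSE)
  if (any(outcomes$n_surveys_observed < 1))
    stop("n_surveys_observed must be >= 1 for every plant", call. = FALSE)
  missing_plant <- setdiff(surveys$plant_id, outcomes$plant_id)
  if (length(missing_plant))
    stop("surveyed plants missing from outcomes: ",
         paste(utils::head(sort(missing_plant), 5), collapse = ", "),
         call. = FALSE)

  totals <- aggregate(count ~ mesocosm_id + plant_id + plant_species +
                        herbivore_species, data = surveys, FUN = sum)
  mass <- setNames(herbivores$mean_dry_mass_g, herbivores$species)
  n_obs <- setNames(outcomes$n_surveys_observed, outcomes$plant_id)
  totals$biomass_g <- totals$count * mass[totals$herbivore_species] /
    n_obs[totals$plant_id]
  totals <- totals[totals$biomass_g > 0,
                   c("mesocosm_id", "plant_id", "plant_species",
                     "herbivore_species", "biomass_g")]
  totals <- totals[order(totals$mesocosm_id, totals$plant_id,
                         totals$herbivore_species), ]
  rownames(totals) <- NULL
  totals
}

#' Total herbivore biomass per mesocosm
#'
#' Multiplies each herbivore species' mean dry mass by its total abundance
#' across all surveys of the mesocosm and sums over species. Deliberately
#' *not* divided by the number of surveys (the per-plant standardisation is;
#' set `normalize_per_survey = TRUE` for the alternative).
#'
#' @inheritParams standardize_herbivore_biomass
#' @param by_provenance Split totals by herbivore provenance (requires a
#'   `provenance` column in `herbivores`).
#' @param normalize_per_survey Divide by `n_surveys`.
#' @param n_surveys Number of survey occasions (required when normalising).
#' @param mesocosm_ids Optional mesocosm ids to report (zero-biomass
#'   mesocosms are then included as explicit zeros).
#' @return Data frame `mesocosm_id` (, `herbivore_provenance`),
#'   `herbivore_biomass_g`.
#' @export
mesocosm_herbivore_biomass <- function(surveys, herbivores,
                                       by_provenance = FALSE,
                                       normalize_per_survey = FALSE,
                                       n_surveys = NULL,
                                       mesocosm_ids = NULL) {
  .assert_columns(surveys, c("mesocosm_id", "herbivore_species", "count"),
                  "surveys")
  .assert_columns(herbivores, c("species", "mean_dry_mass_g"), "herbivores")
  missing_mass <- setdiff(surveys$herbivore_species, herbivores$species)
  if (length(missing_mass))
    stop("no mean dry mass recorded for herbivore species: ",
         paste(sort(missing_mass), collapse = ", "), call. = FALSE)
  if (normalize_per_survey && is.null(n_surveys))
    stop("n_surveys is required when normalize_per_survey = TRUE",
         call. = FALSE)
  if (is.null(mesocosm_ids)) mesocosm_ids <- sort(unique(surveys$mesocosm_id))

  mass <- setNames(herbivores$mean_dry_mass_g, herbivores$species)
  surveys$biomass <- surveys$count * mass[surveys$herbivore_species]
  empty <- nrow(surveys) == 0L
  if (by_provenance) {
    .assert_columns(herbivores, "provenance", "herbivores")
    prov <- setNames(herbivores$provenance, herbivores$species)
    surveys$herbivore_provenance <- prov[surveys$herbivore_species]
    grid <- expand.grid(mesocosm_id = mesocosm_ids,
                        herbivore_provenance = sort(unique(prov)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    agg <- if (empty) cbind(grid[0, ], biomass = numeric(0))
           else aggregate(biomass ~ mesocosm_id + herbivore_provenance,
                          data = surveys, FUN = sum)
    out <- merge(grid, agg, all.x = TRUE, sort = FALSE)
  } else {
    grid <- data.frame(mesocosm_id = mesocosm_ids, stringsAsFactors = FALSE)
    agg <- if (empty) cbind(grid[0, , drop = FALSE], biomass = numeric(0))
           else aggregate(biomass ~ mesocosm_id, data = surveys, FUN = sum)
    out <- merge(grid, agg, all.x = TRUE, sort = FALSE)
  }
  out$biomass[is.na(out$biomass)] <- 0
  if (normalize_per_survey) out$biomass <- out$biomass / n_surveys
  names(out)[names(out) == "biomass"] <- "herbivore_biomass_g"
  out <- out[do.call(order, out[setdiff(names(out), "herbivore_biomass_g")]), ]
  rownames(out) <- NULL
  out
}

#' Build a per-mesocosm quantitative interaction matrix
#'
#' Assembles the plants x herbivores matrix of standardised herbivore dry
#' biomass (`alpha`) for one mesocosm. Plants are the mesocosm's individuals
#' in lexicographic `plant_id` order (zero-load plants kept as zero rows);
#' herbivore columns default to the species observed in that mesocosm, also
#' sorted.
#'
#' @param std_biomass Output of [standardize_herbivore_biomass()].
#' @param plant_individuals Table of plant individuals with `plant_id`,
#'   `mesocosm_id`, `species`, `provenance`.
#' @param mesocosm_id The mesocosm to assemble.
#' @param herbivores Optional character vector fixing the column set (e.g.
#'   the full herbivore pool); must contain every species observed in the
#'   mesocosm.
#' @return An object of class `interaction_matrix`: list with `mesocosm_id`,
#'   `alpha` (dimnamed numeric matrix), `plant_species`, `plant_provenance`.
#' @export
build_interaction_matrix <- function(std_biomass, plant_individuals,
                                     mesocosm_id, herbivores = NULL) {
  .assert_columns(plant_individuals, c("plant_id", "mesocosm_id", "species"),
                  "plant_individuals")
  plants_m <- plant_individuals[plant_individuals$mesocosm_id == mesocosm_id, ]
  if (nrow(plants_m) == 0L)
    stop("unknown mesocosm_id: ", mesocosm_id, call. = FALSE)
  plants_m <- plants_m[order(plants_m$plant_id), ]
  obs <- std_biomass[std_biomass$mesocosm_id == mesocosm_id, ]
  bad <- setdiff(obs$plant_id, plants_m$plant_id)
  if (length(bad))
    stop("observations reference plants absent from mesocosm ", mesocosm_id,
         ": ", paste(utils::head(sort(bad), 5), collapse = ", "),
         call. = FALSE)
  if (is.null(herbivores)) {
    herbivores <- sort(unique(obs$herbivore_species))
  } else {
    herbivores <- sort(unique(herbivores))
    extra <- setdiff(obs$herbivore_species, herbivores)
    if (length(extra))
      stop("observed herbivores not in the supplied column set: ",
           paste(extra, collapse = ", "), call. = FALSE)
  }
  alpha <- matrix(0, nrow = nrow(plants_m), ncol = length(herbivores),
                  dimnames = list(plants_m$plant_id, herbivores))
  if (nrow(obs))
    alpha[cbind(obs$plant_id, obs$herbivore_species)] <- obs$biomass_g
  structure(list(mesocosm_id = mesocosm_id, alpha = alpha,
                 plant_species = setNames(plants_m$species,
                                          plants_m$plant_id),
                 plant_provenance = if ("provenance" %in% names(plants_m))
                   setNames(plants_m$provenance, plants_m$plant_id) else NULL),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("Interaction matrix for mesocosm %s: %d plants x %d herbivores, total biomass %.4g g\n",
              x$mesocosm_id, nrow(x$alpha), ncol(x$alpha), sum(x$alpha)))
  invisible(x)
}

#' Build interaction matrices for every mesocosm
#'
#' @inheritParams build_interaction_matrix
#' @param mesocosm_ids Mesocosms to assemble; defaults to all in
#'   `plant_individuals`.
#' @return Named list of [build_interaction_matrix()] results.
#' @export
interaction_matrices <- function(std_biomass, plant_individuals,
                                 mesocosm_ids = NULL, herbivores = NULL) {
  if (is.null(mesocosm_ids))
    mesocosm_ids <- sort(unique(plant_individuals$mesocosm_id))
  setNames(lapply(mesocosm_ids, function(m)
    build_interaction_matrix(std_biomass, plant_individuals, m, herbivores)),
    mesocosm_ids)
}

#' Experiment-wide meta-web of realised interactions
#'
#' Binary plant-species x herbivore-species matrix with a 1 wherever the pair
#' was realised (positive standardised biomass) in at least one mesocosm.
#' Defines each herbivore's fundamental host range for zero-filling.
#'
#' @param std_biomass Output of [standardize_herbivore_biomass()] for the
#'   whole experiment.
#' @param plants Plant species table (`species`, `provenance`).
#' @param herbivores Herbivore species table (`species`, `provenance`).
#' @return Binary matrix with `plant_provenance` and `herbivore_provenance`
#'   attributes.
#' @export
build_metaweb <- function(std_biomass, plants, herbivores) {
  .assert_columns(plants, "species", "plants")
  .assert_columns(herbivores, "species", "herbivores")
  mw <- matrix(0L, nrow = nrow(plants), ncol = nrow(herbivores),
               dimnames = list(sort(plants$species),
                               sort(herbivores$species)))
  realised <- unique(std_biomass[std_biomass$biomass_g > 0,
                                 c("plant_species", "herbivore_species")])
  if (nrow(realised))
    mw[cbind(realised$plant_species, realised$herbivore_species)] <- 1L
  if ("provenance" %in% names(plants))
    attr(mw, "plant_provenance") <-
      setNames(plants$provenance, plants$species)[rownames(mw)]
  if ("provenance" %in% names(herbivores))
    attr(mw, "herbivore_provenance") <-
      setNames(herbivores$provenance, herbivores$species)[colnames(mw)]
  mw
}

#' Zero-fill informative absences within the fundamental host range
#'
#' Expands the realised-interaction table to one row per (plant individual,
#' herbivore) pair whose pair of *species* lies inside the supplied host-range
#' web (the meta-web, or the generator's ground truth), with `presence` =
#' biomass > 0. Pairs outside the host range are discarded: their zeroes are
#' uninformative.
#'
#' @param std_biomass Output of [standardize_herbivore_biomass()].
#' @param metaweb Binary plant-species x herbivore-species matrix, e.g. from
#'   [build_metaweb()].
#' @param plant_individuals Plant individual table (`plant_id`,
#'   `mesocosm_id`, `species`, and optionally `provenance`).
#' @return Long data frame `mesocosm_id`, `plant_id`, `plant_species`,
#'   `herbivore_species`, `biomass_g`, `presence`.
#' @export
zero_fill_presence <- function(std_biomass, metaweb, plant_individuals) {
  .assert_columns(plant_individuals, c("plant_id", "mesocosm_id", "species"),
                  "plant_individuals")
  edges <- which(metaweb > 0, arr.ind = TRUE)
  hosts <- data.frame(species = rownames(metaweb)[edges[, 1]],
                      herbivore_species = colnames(metaweb)[edges[, 2]],
                      stringsAsFactors = FALSE)
  out <- merge(plant_individuals[, intersect(names(plant_individuals),
                                             c("plant_id", "mesocosm_id",
                                               "species", "provenance"))],
               hosts, by = "species")
  if (nrow(out) == 0L)
    return(data.frame(mesocosm_id = character(0), plant_id = character(0),
                      plant_species = character(0),
                      herbivore_species = character(0),
                      biomass_g = numeric(0), presence = logical(0)))
  out <- merge(out, std_biomass[, c("plant_id", "herbivore_species",
                                    "biomass_g")],
               by = c("plant_id", "herbivore_species"), all.x = TRUE)
  out$biomass_g[is.na(out$biomass_g)] <- 0
  out$presence <- out$biomass_g > 0
  names(out)[names(out) == "species"] <- "plant_species"
  keep <- c("mesocosm_id", "plant_id", "plant_species",
            if ("provenance" %in% names(out)) "provenance",
            "herbivore_species", "biomass_g", "presence")
  out <- out[order(out$mesocosm_id, out$plant_id, out$herbivore_species),
             keep]
  rownames(out) <- NULL
  out
}

#' Normalised degree of each plant
#'
#' Proportion of the herbivore species active in the mesocosm (at least one
#' interaction) that fed on the focal plant.
#'
#' @param imat An [build_interaction_matrix()] object.
#' @param plant_id Optional single plant id; default returns all plants.
#' @return Named numeric vector in `[0, 1]`; `NA` (with a warning) when the
#'   mesocosm has no active herbivore species.
#' @export
normalized_degree <- function(imat, plant_id = NULL) {
  stopifnot(inherits(imat, "interaction_matrix"))
  active <- sum(colSums(imat$alpha) > 0)
  if (active == 0) {
    warning("mesocosm ", imat$mesocosm_id,
            " has no herbivore species with interactions; ",
            "normalised degree is undefined")
    nd <- setNames(rep(NA_real_, nrow(imat$alpha)), rownames(imat$alpha))
  } else {
    nd <- rowSums(imat$alpha > 0) / active
  }
  if (is.null(plant_id)) nd else nd[[plant_id]]
}

#' Median percent damage for ordinal damage categories
#'
#' Maps the six field categories to the midpoint percent leaf area removed:
#' 0 -> 0, 1 (1-5%) -> 3, 2 (6-25%) -> 15.5, 3 (26-50%) -> 38,
#' 4 (51-75%) -> 63, 5 (>75%) -> 88.
#'
#' @param category Integer vector with values in 0..5.
#' @return Numeric vector of percent damage.
#' @examples
#' damage_category_percent(3)  # 38
#' @export
damage_category_percent <- function(category) {
  map <- c(0, 3, 15.5, 38, 63, 88)
  if (any(is.na(category)) || any(category != as.integer(category)) ||
      any(category < 0 | category > 5))
    stop("damage categories must be integers in 0..5", call. = FALSE)
  map[as.integer(category) + 1L]
}

#' Mean percent leaf damage per plant
#'
#' Converts each survey's ordinal category to its median percent value and
#' averages over the plant's surveys.
#'
#' @param damage Data frame with `plant_id` and `category` (0..5).
#' @param plant_id Optional single plant id; default returns all plants.
#' @return Data frame `plant_id`, `mean_damage_pct` (or a scalar when
#'   `plant_id` is given).
#' @examples
#' d <- data.frame(plant_id = "p", category = c(0, 1, 3))
#' damage_index(d, "p")  # (0 + 3 + 38) / 3
#' @export
damage_index <- function(damage, plant_id = NULL) {
  .assert_columns(damage, c("plant_id", "category"), "damage")
  if (nrow(damage) == 0L) {
    if (!is.null(plant_id)) stop("no damage records for plant ", plant_id,
                                 call. = FALSE)
    return(data.frame(plant_id = character(0),
                      mean_damage_pct = numeric(0)))
  }
  damage$pct <- damage_category_percent(damage$category)
  agg <- aggregate(pct ~ plant_id, data = damage, FUN = mean)
  names(agg)[2] <- "mean_damage_pct"
  if (is.null(plant_id)) return(agg[order(agg$plant_id), ])
  row <- agg$mean_damage_pct[agg$plant_id == plant_id]
  if (length(row) == 0L) stop("no damage records for plant ", plant_id,
                              call. = FALSE)
  row
}

#' Herbivore:plant biomass ratio per plant
#'
#' Total standardised herbivore biomass on a plant divided by the plant's
#' total (above + below ground) biomass.
#'
#' @param std_biomass Output of [standardize_herbivore_biomass()].
#' @param outcomes Plant outcome table with `plant_id`,
#'   `aboveground_biomass_g`, `belowground_biomass_g`.
#' @return Data frame `plant_id`, `herbivore_biomass_g`, `plant_biomass_g`,
#'   `ratio` (NA with a warning for zero plant biomass).
#' @export
biomass_ratio <- function(std_biomass, outcomes) {
  .assert_columns(outcomes, c("plant_id", "aboveground_biomass_g",
                              "belowground_biomass_g"), "outcomes")
  load <- if (nrow(std_biomass))
    aggregate(biomass_g ~ plant_id, data = std_biomass, FUN = sum)
  else data.frame(plant_id = character(0), biomass_g = numeric(0))
  out <- data.frame(plant_id = outcomes$plant_id,
                    plant_biomass_g = outcomes$aboveground_biomass_g +
                      outcomes$belowground_biomass_g,
                    stringsAsFactors = FALSE)
  out <- merge(out, load, by = "plant_id", all.x = TRUE)
  out$biomass_g[is.na(out$biomass_g)] <- 0
  names(out)[names(out) == "biomass_g"] <- "herbivore_biomass_g"
  out$ratio <- ifelse(out$plant_biomass_g > 0,
                      out$herbivore_biomass_g / out$plant_biomass_g, NA_real_)
  if (anyNA(out$ratio))
    warning(sum(is.na(out$ratio)),
            " plant(s) with zero biomass; ratio set to NA")
  out <- out[order(out$plant_id),
             c("plant_id", "herbivore_biomass_g", "plant_biomass_g", "ratio")]
  rownames(out) <- NULL
  out
}
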