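#' Generate the factorial mesocosm design
#'
#' Draws the plant and herbivore species pools, composes plant communities on
#' orthogonal exotic and woody gradients, and crosses them with the herbivore
#' and soil treatments and replicates to give the full set of mesocosms. With
#' the default configuration this reproduces the reference structure: a
#' 39-species plant pool (19 native, 20 exotic), 20 communities of 8 species
#' spanning 0--100% exotic and 0--63% woody, a 20-species herbivore pool
#' (7 native, 13 exotic; 13 added, 7 self-colonised) with fundamental host
#' ranges, and 20 x 2 x 2 x 2 = 160 mesocosms.
#'
#' Every plant individual (one per species per mesocosm) receives a stable
#' `plant_id` of the form `<mesocosm_id>_<species>`.
#'
#' @param config A [mesocosm_config()] object.
#' @return An object of class `mesocosm_design`: a list with data frames
#'   `plants` (species, provenance, functional_group), `herbivores` (species,
#'   provenance, mean_dry_mass_g, guild, origin), `host_ranges` (long table of
#'   herbivore fundamental host ranges -- the generator's ground truth),
#'   `communities`, `community_members`, `mesocosms` and `plant_individuals`,
#'   plus the `config`.
#' @examples
#' d <- generate_design(mesocosm_config(seed = 1))
#' nrow(d$mesocosms)   # 160
#' @export
generate_design <- function(config) {
  stopifnot(inherits(config, "mesocosm_config"))

  plants <- .make_plant_pool(config)
  herbivores <- .with_seed(.substream_seed(config$seed, "herbivore_pool"),
                           .make_herbivore_pool(config, plants))
  communities <- .make_communities(config, plants)

  mesocosms <- expand.grid(replicate = seq_len(config$replicates),
                           soil_treatment = config$soil_treatments,
                           herbivore_treatment = config$herbivore_treatments,
                           community_id = communities$communities$community_id,
                           KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)
  mesocosms <- mesocosms[, c("community_id", "herbivore_treatment",
                             "soil_treatment", "replicate")]
  mesocosms$mesocosm_id <- sprintf("M%03d", seq_len(nrow(mesocosms)))
  mesocosms <- merge(mesocosms,
                     communities$communities[, c("community_id",
                                                 "prop_exotic_planted",
                                                 "prop_woody_planted")],
                     by = "community_id", sort = FALSE)
  mesocosms <- mesocosms[order(mesocosms$mesocosm_id),
                         c("mesocosm_id", "community_id",
                           "herbivore_treatment", "soil_treatment",
                           "replicate", "prop_exotic_planted",
                           "prop_woody_planted")]
  rownames(mesocosms) <- NULL

  members <- communities$members
  idx <- merge(mesocosms[, c("mesocosm_id", "community_id")], members,
               by = "community_id", sort = FALSE)
  idx <- merge(idx, plants, by = "species", sort = FALSE)
  idx$plant_id <- paste(idx$mesocosm_id, idx$species, sep = "_")
  plant_individuals <- idx[order(idx$mesocosm_id, idx$position),
                           c("plant_id", "mesocosm_id", "species",
                             "provenance", "functional_group")]
  rownames(plant_individuals) <- NULL

  structure(list(plants = plants,
                 herbivores = herbivores$pool,
                 host_ranges = herbivores$host_ranges,
                 communities = communities$communities,
                 community_members = members,
                 mesocosms = mesocosms,
                 plant_individuals = plant_individuals,
                 config = config),
            class = "mesocosm_design")
}

#' @export
print.mesocosm_design <- function(x, ...) {
  cat(sprintf("Mesocosm design: %d mesocosms, %d communities of %d species,\n",
              nrow(x$mesocosms), nrow(x$communities),
              x$config$community_size))
  cat(sprintf("  plant pool %d (%d native / %d exotic), herbivore pool %d (%d native / %d exotic)\n",
              nrow(x$plants), sum(x$plants$provenance == "native"),
              sum(x$plants$provenance == "exotic"), nrow(x$herbivores),
              sum(x$herbivores$provenance == "native"),
              sum(x$herbivores$provenance == "exotic")))
  invisible(x)
}

#' @keywords internal
#' @noRd
.make_plant_pool <- function(cfg) {
  species <- c(sprintf("nat%02d", seq_len(cfg$n_native_plants)),
               sprintf("exo%02d", seq_len(cfg$n_exotic_plants)))
  provenance <- rep(c("native", "exotic"),
                    c(cfg$n_native_plants, cfg$n_exotic_plants))
  fg <- c(rep(c("woody", "herbaceous"),
              c(cfg$n_woody_native, cfg$n_native_plants - cfg$n_woody_native)),
          rep(c("woody", "herbaceous"),
              c(cfg$n_woody_exotic, cfg$n_exotic_plants - cfg$n_woody_exotic)))
  data.frame(species = species, provenance = provenance,
             functional_group = fg, stringsAsFactors = FALSE)
}

#' @keywords internal
#' @noRd
.make_herbivore_pool <- function(cfg, plants) {
  n <- cfg$n_native_herbivores + cfg$n_exotic_herbivores
  species <- c(sprintf("hn%02d", seq_len(cfg$n_native_herbivores)),
               sprintf("he%02d", seq_len(cfg$n_exotic_herbivores)))
  provenance <- rep(c("native", "exotic"),
                    c(cfg$n_native_herbivores, cfg$n_exotic_herbivores))
  origin <- rep("self_colonised", n)
  origin[sample.int(n, cfg$n_added_herbivores)] <- "added"
  pool <- data.frame(species = species,
                     provenance = provenance,
                     mean_dry_mass_g = rlnorm(n, cfg$herbivore_mass_meanlog,
                                              cfg$herbivore_mass_sdlog),
                     guild = sample(c("leaf_chewer", "root_chewer",
                                      "sucker", "miner"), n, replace = TRUE),
                     origin = origin,
                     stringsAsFactors = FALSE)
  sizes <- sample(seq(cfg$host_range_size[1], cfg$host_range_size[2]),
                  n, replace = TRUE)
  sizes <- pmin(sizes, nrow(plants))
  host_ranges <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(herbivore_species = species[i],
               plant_species = sort(sample(plants$species, sizes[i])),
               stringsAsFactors = FALSE)
  }))
  list(pool = pool, host_ranges = host_ranges)
}

# Communities are laid out on a balanced grid of exotic levels
# {0, .25, .5, .75, 1} x woody levels {0, .125, .375, .625} so that the two
# planted gradients are exactly orthogonal at the default 20 communities.

#' @keywords internal
#' @noRd
.make_communities <- function(cfg, plants) {
  size <- cfg$community_size
  exotic_levels <- c(0, 0.25, 0.5, 0.75, 1)
  woody_levels <- c(0, 0.125, 0.375, 0.625)
  k <- seq_len(cfg$n_communities) - 1L
  e_idx <- (k %% length(exotic_levels)) + 1L
  w_idx <- ((k %/% length(exotic_levels)) %% length(woody_levels)) + 1L
  n_exotic <- round(exotic_levels[e_idx] * size)
  n_woody <- round(woody_levels[w_idx] * size)

  pools <- split(plants$species, paste(plants$provenance,
                                       plants$functional_group))
  avail <- vapply(pools, length, 1L)

  members <- vector("list", cfg$n_communities)
  for (i in seq_len(cfg$n_communities)) {
    ne <- n_exotic[i]; nn <- size - ne; w <- n_woody[i]
    we_lo <- max(0L, w - min(nn, length(pools[["native woody"]])))
    we_hi <- min(ne, w, length(pools[["exotic woody"]]))
    if (we_lo > we_hi)
      stop(sprintf(paste("cannot place community %d on both gradients:",
                         "%d exotic and %d woody species requested but the",
                         "pool cannot supply them"), i, ne, w), call. = FALSE)
    we <- min(max(round(w * ne / size), we_lo), we_hi)
    wn <- w - we
    draw <- function(pool, m) {
      if (m > length(pool))
        stop(sprintf("community %d needs %d species from a pool of %d",
                     i, m, length(pool)), call. = FALSE)
      if (m == 0L) character(0) else sample(pool, m)
    }
    sp <- .with_seed(.substream_seed(cfg$seed, paste0("community", i)), {
      c(draw(pools[["exotic woody"]], we),
        draw(pools[["exotic herbaceous"]], ne - we),
        draw(pools[["native woody"]], wn),
        draw(pools[["native herbaceous"]], nn - wn))
    })
    members[[i]] <- data.frame(community_id = i, species = sp,
                               position = seq_along(sp),
                               stringsAsFactors = FALSE)
  }
  members <- do.call(rbind, members)

  communities <- data.frame(community_id = seq_len(cfg$n_communities),
                            prop_exotic_planted = n_exotic / size,
                            prop_woody_planted = n_woody / size)
  if (isTRUE(sd(communities$prop_exotic_planted) > 0) &&
      isTRUE(sd(communities$prop_woody_planted) > 0)) {
    r <- cor(communities$prop_exotic_planted, communities$prop_woody_planted)
    if (abs(r) > cfg$orthogonality_bound)
      stop(sprintf(paste("exotic and woody gradients are not orthogonal",
                         "(|cor| = %.3f > %.3f); adjust n_communities"),
                   abs(r), cfg$orthogonality_bound), call. = FALSE)
  }
  list(communities = communities, members = members)
}
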