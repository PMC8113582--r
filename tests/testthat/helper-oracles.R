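# Independent oracles and small fixtures shared across test files.

# Literal triple-loop evaluation of the pairwise PAC definition, with 0/0
# terms defined as 0. Kept deliberately naive and independent of the
# vectorised implementation.
pac_triple_loop <- function(alpha) {
  H <- nrow(alpha); P <- ncol(alpha)
  d <- matrix(0, H, H, dimnames = list(rownames(alpha), rownames(alpha)))
  row_tot <- rowSums(alpha)
  col_tot <- colSums(alpha)
  for (i in seq_len(H)) for (j in seq_len(H)) {
    acc <- 0
    for (k in seq_len(P)) {
      if (row_tot[i] > 0 && col_tot[k] > 0)
        acc <- acc + (alpha[i, k] / row_tot[i]) * (alpha[j, k] / col_tot[k])
    }
    d[i, j] <- acc
  }
  d
}

# Naive per-record accumulation of an interaction matrix.
accumulate_matrix <- function(std, plant_ids, herbivores) {
  m <- matrix(0, length(plant_ids), length(herbivores),
              dimnames = list(sort(plant_ids), sort(herbivores)))
  for (r in seq_len(nrow(std)))
    m[std$plant_id[r], std$herbivore_species[r]] <-
      m[std$plant_id[r], std$herbivore_species[r]] + std$biomass_g[r]
  m
}

# Small, fast generator configuration used across tests.
small_config <- function(seed = 1, ...) {
  mesocosm_config(seed = seed, n_communities = 5, replicates = 1,
                  soil_treatments = "home", n_surveys = 4,
                  death_prob = 0, ...)
}

# Provenance-neutral configuration (all multipliers 1, equal growth).
neutral_config <- function(seed = 1, ...) {
  mesocosm_config(seed = seed,
                  exotic_interaction_odds_multiplier = 1,
                  exotic_biomass_multiplier = 1,
                  exotic_herbivore_prop_exotic_slope = 0,
                  herbivory_biomass_penalty_exotic = 0,
                  plant_growth = list(native_meanlog = log(5),
                                      exotic_meanlog = log(5), sdlog = 0.8),
                  damage_category_probabilities = list(
                    native = c(0.7, 0.2, 0.07, 0.02, 0.007, 0.003),
                    exotic = c(0.7, 0.2, 0.07, 0.02, 0.007, 0.003)),
                  ...)
}

# Random sparse non-negative biomass matrix.
random_alpha <- function(H, P, density = 0.5) {
  a <- matrix(runif(H * P) * (runif(H * P) < density), H, P)
  dimnames(a) <- list(sprintf("p%02d", seq_len(H)),
                      sprintf("h%02d", seq_len(P)))
  a
}
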