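test_that("design invariants hold on a reduced design", {
  d <- generate_design(small_config(seed = 11))
  expect_equal(nrow(d$mesocosms), 5 * 2 * 1 * 1)
  tab <- table(d$community_members$community_id)
  expect_true(all(tab == 8))
  # prop_exotic_planted equals exotic member count / community size
  prov <- setNames(d$plants$provenance, d$plants$species)
  for (cid in d$communities$community_id) {
    members <- d$community_members$species[
      d$community_members$community_id == cid]
    expect_equal(mean(prov[members] == "exotic"),
                 d$communities$prop_exotic_planted[
                   d$communities$community_id == cid])
  }
  expect_false(anyDuplicated(d$plant_individuals$plant_id) > 0)
  # every herbivore has a non-empty host range and positive mass
  expect_true(all(table(d$host_ranges$herbivore_species) >= 1))
  expect_true(all(d$herbivores$mean_dry_mass_g > 0))
})

test_that("exotic and woody gradients are orthogonal at the default layout", {
  d <- generate_design(mesocosm_config(seed = 4))
  expect_equal(cor(d$communities$prop_exotic_planted,
                   d$communities$prop_woody_planted), 0)
  expect_true(all(d$communities$prop_woody_planted <= 0.63))
})

test_that("degenerate design gives a single mesocosm", {
  cfg <- mesocosm_config(seed = 1, n_communities = 1, replicates = 1,
                         herbivore_treatments = "plus_H",
                         soil_treatments = "home")
  d <- generate_design(cfg)
  expect_equal(nrow(d$mesocosms), 1)
  expect_equal(nrow(d$plant_individuals), 8)
})

test_that("same seed reproduces the experiment byte for byte", {
  a <- simulate_mesocosm_experiment(small_config(seed = 42))
  b <- simulate_mesocosm_experiment(small_config(seed = 42))
  expect_identical(a$surveys, b$surveys)
  expect_identical(a$damage, b$damage)
  expect_identical(a$outcomes, b$outcomes)
  c <- simulate_mesocosm_experiment(small_config(seed = 43))
  expect_false(identical(a$surveys, c$surveys))
})

test_that("per-mesocosm substreams are stable under design subsetting", {
  cfg <- small_config(seed = 9)
  full <- simulate_surveys(generate_design(cfg))
  # a design with fewer communities still contains mesocosms M001..M002
  cfg2 <- mesocosm_config(seed = 9, n_communities = 2, replicates = 1,
                          soil_treatments = "home", n_surveys = 4,
                          death_prob = 0)
  sub <- simulate_surveys(generate_design(cfg2))
  keep <- full[full$mesocosm_id %in% sub$mesocosm_id, ]
  rownames(keep) <- NULL
  attr(keep, "plant_schedule") <- NULL
  attr(sub, "plant_schedule") <- NULL
  expect_identical(keep, sub)
})

test_that("surveys are closed over the fundamental host ranges", {
  ex <- simulate_mesocosm_experiment(small_config(seed = 5))
  key <- paste(ex$surveys$plant_species, ex$surveys$herbivore_species)
  truth <- paste(ex$design$host_ranges$plant_species,
                 ex$design$host_ranges$herbivore_species)
  expect_true(all(key %in% truth))
  expect_true(all(ex$surveys$count >= 1))
})

test_that("retention 0 silences all -Herbivore mesocosms", {
  cfg <- small_config(seed = 6, minus_H_presence_retention = 0)
  d <- generate_design(cfg)
  s <- simulate_surveys(d)
  minus <- d$mesocosms$mesocosm_id[d$mesocosms$herbivore_treatment ==
                                     "minus_H"]
  expect_equal(sum(s$mesocosm_id %in% minus), 0)
  expect_gt(sum(!(s$mesocosm_id %in% minus)), 0)
})

test_that("odds multiplier 1 gives equal presence rates on exotics and natives", {
  cfg <- mesocosm_config(seed = 21, n_communities = 10, replicates = 2,
                         soil_treatments = "home", n_surveys = 8,
                         death_prob = 0,
                         exotic_interaction_odds_multiplier = 1,
                         exotic_herbivore_prop_exotic_slope = 0)
  d <- generate_design(cfg)
  s <- simulate_surveys(d)
  pres <- survey_presence_records(s, d)
  plus <- pres[pres$herbivore_treatment == "plus_H", ]
  p_exo <- mean(plus$presence[plus$plant_exotic == 1])
  p_nat <- mean(plus$presence[plus$plant_exotic == 0])
  n_exo <- sum(plus$plant_exotic == 1)
  n_nat <- sum(plus$plant_exotic == 0)
  se <- sqrt(p_exo * (1 - p_exo) / n_exo + p_nat * (1 - p_nat) / n_nat)
  expect_lt(abs(p_exo - p_nat), 3 * se)
})

test_that("biomass penalty is recovered and vanishes when switched off", {
  cfg <- mesocosm_config(seed = 31, n_communities = 10, replicates = 2,
                         soil_treatments = "home", n_surveys = 2,
                         death_prob = 0)
  ex <- simulate_mesocosm_experiment(cfg)
  est <- estimate_generator_effects(ex)
  expect_lt(abs(est$biomass_penalty - 0.31), 0.08)

  cfg0 <- mesocosm_config(seed = 31, n_communities = 10, replicates = 2,
                          soil_treatments = "home", n_surveys = 2,
                          death_prob = 0,
                          herbivory_biomass_penalty_exotic = 0)
  est0 <- estimate_generator_effects(simulate_mesocosm_experiment(cfg0))
  expect_lt(abs(est0$biomass_penalty), 0.1)
})

test_that("death probability 0 keeps every plant alive for all surveys", {
  ex <- simulate_mesocosm_experiment(small_config(seed = 8))
  expect_true(all(ex$outcomes$alive))
  expect_true(all(ex$outcomes$n_surveys_observed == 4))
  expect_true(all(ex$outcomes$aboveground_biomass_g +
                    ex$outcomes$belowground_biomass_g > 0))
  # and a positive death probability exercises the early-death branch
  ex2 <- simulate_mesocosm_experiment(
    mesocosm_config(seed = 8, n_communities = 5, replicates = 1,
                    soil_treatments = "home", n_surveys = 4,
                    death_prob = 0.5))
  dead <- ex2$outcomes[!ex2$outcomes$alive, ]
  expect_gt(nrow(dead), 0)
  expect_true(all(dead$n_surveys_observed < 4))
  expect_true(all(dead$aboveground_biomass_g == 0))
})

test_that("damage categories stay in range and respond to treatment", {
  ex <- simulate_mesocosm_experiment(small_config(seed = 13))
  expect_true(all(ex$damage$category %in% 0:5))
  meso <- ex$design$mesocosms
  dmg <- merge(ex$damage, meso[, c("mesocosm_id", "herbivore_treatment")])
  mean_plus <- mean(dmg$category[dmg$herbivore_treatment == "plus_H"])
  mean_minus <- mean(dmg$category[dmg$herbivore_treatment == "minus_H"])
  expect_gt(mean_plus, mean_minus)
})

test_that("invalid configurations are rejected", {
  expect_error(mesocosm_config(presence_base_prob = 1.5), "probabilities")
  expect_error(mesocosm_config(exotic_biomass_multiplier = -1), "> 0")
  expect_error(mesocosm_config(count_mean_native = 0.5), "exceed 1")
  expect_error(mesocosm_config(n_woody_native = 25), "woody")
})
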