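make_surveys <- function(counts, plant = "M1_a", species = "a",
                         herb = "h1", meso = "M1") {
  data.frame(mesocosm_id = meso, survey_index = seq_along(counts),
             plant_id = plant, plant_species = species,
             herbivore_species = herb, count = counts,
             stringsAsFactors = FALSE)
}

test_that("biomass standardisation follows the survey-count formula", {
  herb <- data.frame(species = c("h1", "h2"),
                     mean_dry_mass_g = c(0.02, 0.1))
  # counts (2,3,5) over 8 surveys at 0.02 g -> 10 * 0.02 / 8
  s <- make_surveys(c(2, 3, 5))
  o <- data.frame(plant_id = "M1_a", n_surveys_observed = 8)
  expect_equal(standardize_herbivore_biomass(s, herb, o)$biomass_g, 0.025)
  # plant that died after 4 surveys: (4+4) * 0.1 / 4
  s2 <- make_surveys(c(4, 4, 0, 0), herb = "h2")
  o2 <- data.frame(plant_id = "M1_a", n_surveys_observed = 4)
  expect_equal(standardize_herbivore_biomass(s2, herb, o2)$biomass_g, 0.2)
  # all-zero counts vanish from the (zero-omitted) output
  s3 <- make_surveys(c(0, 0))
  expect_equal(nrow(standardize_herbivore_biomass(s3, herb, o)), 0)
  # record order does not matter
  s4 <- rbind(make_surveys(c(2, 3, 5)), make_surveys(c(1, 1), herb = "h2"))
  shuffled <- s4[c(4, 1, 5, 3, 2), ]
  expect_equal(standardize_herbivore_biomass(s4, herb, o),
               standardize_herbivore_biomass(shuffled, herb, o))
})

test_that("a herbivore without a mass record is a named hard error", {
  s <- make_surveys(3, herb = "mystery_bug")
  o <- data.frame(plant_id = "M1_a", n_surveys_observed = 8)
  expect_error(standardize_herbivore_biomass(
    s, data.frame(species = "h1", mean_dry_mass_g = 0.1), o),
    "mystery_bug")
})

test_that("mesocosm totals are additive and not survey-normalised", {
  herb <- data.frame(species = c("h1", "h2"),
                     mean_dry_mass_g = c(0.02, 0.05))
  s <- rbind(make_surveys(c(4, 6)),                  # 10 * 0.02 = 0.2
             make_surveys(c(2, 2), herb = "h2"))     #  4 * 0.05 = 0.2
  out <- mesocosm_herbivore_biomass(s, herb)
  expect_equal(out$herbivore_biomass_g, 0.4)
  # empty mesocosm reported as exact zero
  out2 <- mesocosm_herbivore_biomass(s, herb, mesocosm_ids = c("M1", "M9"))
  expect_equal(out2$herbivore_biomass_g[out2$mesocosm_id == "M9"], 0)
  # optional per-survey normalisation
  out3 <- mesocosm_herbivore_biomass(s, herb, normalize_per_survey = TRUE,
                                     n_surveys = 2)
  expect_equal(out3$herbivore_biomass_g, 0.2)
  # provenance split sums back to the total
  herb$provenance <- c("native", "exotic")
  out4 <- mesocosm_herbivore_biomass(s, herb, by_provenance = TRUE)
  expect_equal(sum(out4$herbivore_biomass_g), 0.4)
  expect_equal(out4$herbivore_biomass_g[out4$herbivore_provenance ==
                                          "exotic"], 0.2)
})

test_that("interaction matrices match a naive accumulation oracle", {
  plants <- data.frame(plant_id = paste0("M1_", letters[1:4]),
                       mesocosm_id = "M1", species = letters[1:4],
                       provenance = "native", stringsAsFactors = FALSE)
  set.seed(99)
  std <- data.frame(mesocosm_id = "M1",
                    plant_id = sample(plants$plant_id, 6, replace = TRUE),
                    herbivore_species = sample(c("h1", "h2", "h3"), 6,
                                               replace = TRUE),
                    biomass_g = runif(6), stringsAsFactors = FALSE)
  std <- aggregate(biomass_g ~ mesocosm_id + plant_id + herbivore_species,
                   data = std, FUN = sum)
  std$plant_species <- sub("M1_", "", std$plant_id)
  im <- build_interaction_matrix(std, plants, "M1",
                                 herbivores = c("h1", "h2", "h3"))
  oracle <- accumulate_matrix(std, plants$plant_id, c("h1", "h2", "h3"))
  expect_equal(im$alpha, oracle)
  # permuting the input rows changes nothing
  im2 <- build_interaction_matrix(std[sample(nrow(std)), ], plants, "M1",
                                  herbivores = c("h1", "h2", "h3"))
  expect_identical(im$alpha, im2$alpha)
})

test_that("matrix construction keeps zero rows and flags foreign plants", {
  plants <- data.frame(plant_id = c("M1_a", "M1_b"), mesocosm_id = "M1",
                       species = c("a", "b"), provenance = "native")
  std <- data.frame(mesocosm_id = "M1", plant_id = "M1_a",
                    plant_species = "a", herbivore_species = "h1",
                    biomass_g = 0.025)
  im <- build_interaction_matrix(std, plants, "M1")
  expect_equal(dim(im$alpha), c(2L, 1L))
  expect_equal(unname(im$alpha["M1_b", ]), 0)
  # no observations at all -> all-zero matrix of the requested dimensions
  im0 <- build_interaction_matrix(std[0, ], plants, "M1",
                                  herbivores = c("h1", "h2"))
  expect_equal(im0$alpha, matrix(0, 2, 2,
                                 dimnames = list(c("M1_a", "M1_b"),
                                                 c("h1", "h2"))))
  std_bad <- transform(std, plant_id = "M2_z")
  expect_error(build_interaction_matrix(std_bad, plants, "M1"), "M2_z")
})

test_that("the meta-web is a monotone union of realised interactions", {
  plants <- data.frame(species = c("a", "b"),
                       provenance = c("native", "exotic"))
  herbs <- data.frame(species = c("h1", "h2"), provenance = "native")
  std <- data.frame(mesocosm_id = c("M1", "M2"),
                    plant_id = c("M1_a", "M2_a"),
                    plant_species = "a", herbivore_species = "h1",
                    biomass_g = c(0.01, 0.02))
  mw <- build_metaweb(std, plants, herbs)
  expect_equal(mw["a", "h1"], 1L)   # realised in at least one mesocosm
  expect_equal(mw["b", "h2"], 0L)   # never realised
  # adding observations never removes an edge
  more <- rbind(std, data.frame(mesocosm_id = "M3", plant_id = "M3_b",
                                plant_species = "b",
                                herbivore_species = "h2", biomass_g = 1))
  mw2 <- build_metaweb(more, plants, herbs)
  expect_true(all(mw2[mw == 1L] == 1L))
})

test_that("the realised meta-web is contained in the generator truth", {
  ex <- simulate_mesocosm_experiment(small_config(seed = 17))
  std <- standardize_herbivore_biomass(ex$surveys, ex$design$herbivores,
                                       ex$outcomes)
  mw <- build_metaweb(std, ex$design$plants, ex$design$herbivores)
  truth <- truth_host_web(ex$design)
  expect_true(all(mw <= truth[rownames(mw), colnames(mw)]))
})

test_that("zero filling enumerates exactly the in-range pairs", {
  plants <- data.frame(plant_id = paste0("M1_", letters[1:8]),
                       mesocosm_id = "M1", species = letters[1:8],
                       provenance = "native", stringsAsFactors = FALSE)
  mw <- matrix(0L, 8, 2, dimnames = list(letters[1:8], c("h1", "h2")))
  mw[c("a", "c", "e"), "h1"] <- 1L
  std <- data.frame(mesocosm_id = "M1", plant_id = "M1_a",
                    plant_species = "a", herbivore_species = "h1",
                    biomass_g = 0.5)
  zf <- zero_fill_presence(std, mw, plants)
  expect_equal(sum(zf$herbivore_species == "h1"), 3)  # 3 fundamental hosts
  expect_equal(sum(zf$herbivore_species == "h2"), 0)
  expect_equal(zf$presence, zf$biomass_g > 0)
  expect_equal(sum(zf$presence), 1)
  # all-ones web -> plants x herbivores rows; all-zero web -> empty
  expect_equal(nrow(zero_fill_presence(std, (mw * 0L) + 1L, plants)), 16)
  expect_equal(nrow(zero_fill_presence(std, mw * 0L, plants)), 0)
})

test_that("normalised degree counts active herbivores only", {
  alpha <- matrix(0, 3, 8, dimnames = list(paste0("p", 1:3),
                                           paste0("h", 1:8)))
  alpha[1, 1:4] <- 1   # fed on by 4 of 8
  alpha[3, 1:8] <- 1   # fed on by all
  im <- structure(list(mesocosm_id = "M1", alpha = alpha,
                       plant_species = setNames(paste0("s", 1:3),
                                                rownames(alpha))),
                  class = "interaction_matrix")
  nd <- normalized_degree(im)
  expect_equal(unname(nd), c(0.5, 0, 1))
  expect_equal(normalized_degree(im, "p1"), 0.5)
  im$alpha[] <- 0
  expect_warning(nd0 <- normalized_degree(im), "undefined")
  expect_true(all(is.na(nd0)))
})

test_that("damage categories map to midpoint percentages", {
  expect_equal(damage_category_percent(3), 38)
  expect_equal(damage_category_percent(0:5), c(0, 3, 15.5, 38, 63, 88))
  expect_error(damage_category_percent(7), "0..5")
  d <- data.frame(plant_id = "p", category = c(0, 1, 3))
  expect_equal(damage_index(d, "p"), (0 + 3 + 38) / 3)
  expect_equal(damage_index(data.frame(plant_id = "p",
                                       category = c(0, 0, 0)), "p"), 0)
  expect_error(damage_index(data.frame(plant_id = "p", category = 6L)),
               "0..5")
})

test_that("herbivore:plant biomass ratio behaves and scales", {
  std <- data.frame(mesocosm_id = "M1", plant_id = "M1_a",
                    plant_species = "a", herbivore_species = "h1",
                    biomass_g = 0.5)
  o <- data.frame(plant_id = c("M1_a", "M1_b"),
                  aboveground_biomass_g = c(6, 1),
                  belowground_biomass_g = c(4, 1))
  br <- biomass_ratio(std, o)
  expect_equal(br$ratio[br$plant_id == "M1_a"], 0.05)
  expect_equal(br$ratio[br$plant_id == "M1_b"], 0)  # zero herbivores
  # doubling both biomasses leaves the ratio unchanged
  br2 <- biomass_ratio(transform(std, biomass_g = biomass_g * 2),
                       transform(o, aboveground_biomass_g =
                                   aboveground_biomass_g * 2,
                                 belowground_biomass_g =
                                   belowground_biomass_g * 2))
  expect_equal(br2$ratio, br$ratio)
  o$aboveground_biomass_g[1] <- 0; o$belowground_biomass_g[1] <- 0
  expect_warning(br3 <- biomass_ratio(std, o), "zero biomass")
  expect_true(is.na(br3$ratio[br3$plant_id == "M1_a"]))
})

test_that("standardised biomass conserves total counts when no plant died", {
  ex <- simulate_mesocosm_experiment(small_config(seed = 23))
  std <- standardize_herbivore_biomass(ex$surveys, ex$design$herbivores,
                                       ex$outcomes)
  mass <- setNames(ex$design$herbivores$mean_dry_mass_g,
                   ex$design$herbivores$species)
  for (h in unique(std$herbivore_species)) {
    lhs <- sum(std$biomass_g[std$herbivore_species == h]) * 4  # n_surveys
    rhs <- sum(ex$surveys$count[ex$surveys$herbivore_species == h]) * mass[h]
    expect_equal(lhs, unname(rhs))
  }
})
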