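test_that("hand-computed pairwise PAC values are reproduced", {
  # two plants, one shared herbivore, equal loads -> every d is 0.5
  a <- matrix(c(1, 1), nrow = 2, dimnames = list(c("p1", "p2"), "h1"))
  d <- pairwise_pac(a)
  expect_equal(unname(d), matrix(0.5, 2, 2))
  # plants sharing no herbivores have d = 0
  b <- diag(c(2, 3))
  dimnames(b) <- list(c("p1", "p2"), c("h1", "h2"))
  db <- pairwise_pac(b)
  expect_equal(db["p1", "p2"], 0)
  expect_equal(db["p2", "p1"], 0)
  expect_equal(diag(db), c(p1 = 1, p2 = 1))
  # A(2 on h1), B(1 on h1, 1 on h2), C(1 on h2)
  abc <- matrix(c(2, 0,
                  1, 1,
                  0, 1), nrow = 3, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), c("h1", "h2")))
  dd <- pairwise_pac(abc)
  expect_equal(dd["A", "B"], 1 / 3)
  expect_equal(dd["B", "A"], 1 / 3)
  expect_equal(dd["A", "C"], 0)
})

test_that("vectorised PAC equals the triple-loop oracle", {
  set.seed(202)
  for (i in 1:50) {
    a <- random_alpha(sample(2:8, 1), sample(2:20, 1),
                      density = runif(1, 0.2, 0.9))
    expect_equal(pairwise_pac(a), pac_triple_loop(a), tolerance = 1e-12)
  }
})

test_that("rows of d sum to one for plants with positive load", {
  set.seed(303)
  for (i in 1:50) {
    a <- random_alpha(sample(2:8, 1), sample(2:20, 1),
                      density = runif(1, 0.2, 0.9))
    d <- pairwise_pac(a)
    loaded <- rowSums(a) > 0
    if (any(loaded))
      expect_equal(unname(rowSums(d)[loaded]),
                   rep(1, sum(loaded)), tolerance = 1e-12)
    if (any(!loaded))
      expect_equal(unname(rowSums(d)[!loaded]), rep(0, sum(!loaded)))
    expect_true(all(d >= 0 & d <= 1 + 1e-12))
  }
})

test_that("d is scale invariant and the aggregates scale linearly", {
  set.seed(404)
  a <- random_alpha(6, 10)
  d1 <- pairwise_pac(a)
  d2 <- pairwise_pac(a * 7.3)
  expect_equal(d1, d2, tolerance = 1e-12)
  p1 <- aggregate_pac(d1, a)
  p2 <- aggregate_pac(d2, a * 7.3)
  expect_equal(p2$pac_exerted, p1$pac_exerted * 7.3, tolerance = 1e-12)
  expect_equal(p2$pac_received, p1$pac_received * 7.3, tolerance = 1e-12)
})

test_that("relabelling plants permutes d accordingly", {
  set.seed(505)
  a <- random_alpha(5, 8)
  perm <- sample(nrow(a))
  d <- pairwise_pac(a)
  dp <- pairwise_pac(a[perm, ])
  expect_equal(dp, d[perm, perm], tolerance = 1e-12)
})

test_that("aggregation weights, excludes the diagonal, and handles limits", {
  a <- matrix(c(1, 1), nrow = 2, dimnames = list(c("p1", "p2"), "h1"))
  pr <- aggregate_pac(pairwise_pac(a), a)
  expect_equal(unname(pr$pac_exerted), c(0.5, 0.5))
  expect_equal(unname(pr$pac_received), c(0.5, 0.5))
  expect_equal(unname(pr$focal_biomass), c(1, 1))
  expect_equal(unname(pr$other_biomass), c(1, 1))
  # a plant with zero load exerts nothing
  z <- rbind(a, p3 = c(0))
  prz <- aggregate_pac(pairwise_pac(z), z)
  expect_equal(unname(prz$pac_exerted["p3"]), 0)
  expect_equal(unname(prz$pac_received["p3"]), 0)
  # a single-plant mesocosm has no heterospecific terms
  single <- matrix(2, 1, 1, dimnames = list("p1", "h1"))
  prs <- aggregate_pac(pairwise_pac(single), single)
  expect_equal(unname(prs$pac_exerted), 0)
  expect_equal(unname(prs$pac_received), 0)
  expect_error(aggregate_pac(matrix(0, 3, 3), a), "square")
  expect_error(pairwise_pac(matrix(-1, 2, 2)), "non-negative")
})

test_that("direction flag swaps exerted and received", {
  set.seed(606)
  a <- random_alpha(5, 6)
  d <- pairwise_pac(a)
  m <- aggregate_pac(d, a, direction = "muller")
  t_ <- aggregate_pac(d, a, direction = "transposed")
  expect_equal(m$share_exerted, t_$share_received)
  expect_equal(m$share_received, t_$share_exerted)
})

test_that("retention 0 drives every PAC value to zero in -Herbivore", {
  cfg <- small_config(seed = 77, minus_H_presence_retention = 0)
  ex <- simulate_mesocosm_experiment(cfg)
  std <- standardize_herbivore_biomass(ex$surveys, ex$design$herbivores,
                                       ex$outcomes)
  imats <- interaction_matrices(std, ex$design$plant_individuals)
  pr <- compute_pac(imats)
  pdf <- pac_table(pr, imats, ex$design)
  minus <- pdf[pdf$herbivore_treatment == "minus_H", ]
  expect_true(all(minus$pac_exerted == 0))
  expect_true(all(minus$pac_received == 0))
  plus <- pdf[pdf$herbivore_treatment == "plus_H", ]
  expect_gt(sum(plus$pac_exerted), 0)
})

test_that("treatment summaries honour symmetry and the all-zero group", {
  pdf <- data.frame(provenance = rep(c("native", "exotic"), each = 4),
                    herbivore_treatment = rep(c("plus_H", "minus_H"), 4),
                    soil_treatment = "home",
                    pac_exerted = c(1, 0, 2, 0, 1, 0, 2, 0),
                    pac_received = c(3, 0, 4, 0, 3, 0, 4, 0))
  s <- pac_treatment_summary(pdf)
  # identical native and exotic groups give equal means
  for (tr in c("plus_H", "minus_H")) {
    sub <- s[s$herbivore_treatment == tr, ]
    expect_equal(sub$mean_exerted[1], sub$mean_exerted[2])
  }
  # all-zero -Herbivore group: raw-scale mean 0
  expect_equal(s$mean_exerted[s$herbivore_treatment == "minus_H"], c(0, 0))
  # adding a lone "away" row leaves several empty groups, one warning each
  w <- capture_warnings(
    pac_treatment_summary(rbind(pdf, transform(pdf[1, ],
                                               soil_treatment = "away"))))
  expect_true(all(grepl("empty", w)) && length(w) >= 1)
})

test_that("exotic-biased generation yields higher exotic PAC exerted", {
  cfg <- mesocosm_config(seed = 55, n_communities = 10, replicates = 2,
                         soil_treatments = "home", n_surveys = 8,
                         death_prob = 0)
  ex <- simulate_mesocosm_experiment(cfg)
  std <- standardize_herbivore_biomass(ex$surveys, ex$design$herbivores,
                                       ex$outcomes)
  imats <- interaction_matrices(std, ex$design$plant_individuals)
  pdf <- pac_table(compute_pac(imats), imats, ex$design)
  plus <- pdf[pdf$herbivore_treatment == "plus_H", ]
  expect_gt(mean(plus$pac_exerted[plus$provenance == "exotic"]),
            mean(plus$pac_exerted[plus$provenance == "native"]))
})
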