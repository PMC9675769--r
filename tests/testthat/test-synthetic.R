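test_that("the generator is deterministic under a fixed seed", {
  cfg <- synth_config(n_sites = 2, n_cameras_per_site = 10, n_species = 8,
                      seed = 5)
  c1 <- generate_community(cfg)
  c2 <- generate_community(cfg)
  expect_identical(c1, c2)
  d1 <- simulate_detections(c1)
  d2 <- simulate_detections(c2)
  expect_identical(d1$detections, d2$detections)
})

test_that("a pure-herbivore community has plant fractions at or above 0.80", {
  cfg <- synth_config(guild_proportions = c(carnivore = 0, herbivore = 1,
                                            insectivore = 0, omnivore = 0),
                      n_species = 12, seed = 3)
  com <- generate_community(cfg)
  expect_true(all(com$truth$species$guild == "herbivore"))
  expect_true(all(com$traits$diet_plant >= 0.80))
})

test_that("generated diet fractions always map back to the intended guild", {
  for (seed in 1:5) {
    com <- generate_community(synth_config(n_species = 20, seed = seed))
    derived <- assign_guild(com$traits$diet_vertebrate, com$traits$diet_plant,
                            com$traits$diet_invertebrate)
    expect_equal(derived, com$truth$species$guild)
  }
})

test_that("nocturnal weight increases with mass under a positive slope", {
  cfg <- synth_config(
    guild_proportions = c(carnivore = 0, herbivore = 1, insectivore = 0,
                          omnivore = 0),
    nocturnality_slope_per_guild = c(carnivore = 0, herbivore = 1,
                                     insectivore = 0, omnivore = 0),
    mass_range_g = c(100, 100000), n_species = 30, seed = 2)
  com <- generate_community(cfg)
  sp <- com$truth$species[order(com$truth$species$body_mass_g), ]
  expect_true(all(diff(sp$p_night) > 0))
})

test_that("masses are log-uniform within range and above 75 g", {
  com <- generate_community(synth_config(n_species = 200,
                                         mass_range_g = c(80, 5e5), seed = 8))
  expect_true(all(com$traits$body_mass_g >= 80 &
                    com$traits$body_mass_g <= 5e5))
  expect_error(synth_config(mass_range_g = c(50, 1000)), "75")
})

test_that("invalid guild proportions are rejected", {
  expect_error(synth_config(guild_proportions = c(carnivore = 0.5,
                                                  herbivore = 0.6,
                                                  insectivore = 0,
                                                  omnivore = 0)), "simplex")
})

test_that("fixed photos-per-visit produce exact burst sizes", {
  cfg <- synth_config(n_sites = 1, n_cameras_per_site = 5, n_species = 4,
                      photos_per_visit = 3, photos_fixed = TRUE,
                      base_visit_rate = 0.5, seed = 6)
  com <- generate_community(cfg)
  sim <- simulate_detections(com)
  n_visits <- nrow(sim$visits)
  expect_equal(nrow(sim$detections), 3L * n_visits)
  ev <- independent_events(sim$detections)
  expect_gte(nrow(ev), n_visits * 0.5)  # bursts collapse, visits mostly survive
  expect_lte(nrow(ev), n_visits)
})

test_that("zero visit rate gives an empty detection table", {
  cfg <- synth_config(n_sites = 1, n_cameras_per_site = 5, n_species = 4,
                      base_visit_rate = 0, seed = 6)
  sim <- simulate_detections(generate_community(cfg))
  expect_equal(nrow(sim$detections), 0L)
})

test_that("a purely nocturnal species is classified night downstream", {
  cfg <- synth_config(
    n_sites = 1, site_latitudes = 0, site_longitudes = 0,
    n_cameras_per_site = 30, n_species = 2,
    guild_proportions = c(carnivore = 0, herbivore = 1, insectivore = 0,
                          omnivore = 0),
    nocturnality_intercept_per_guild = c(carnivore = 0, herbivore = 12,
                                         insectivore = 0, omnivore = 0),
    nocturnality_slope_per_guild = c(carnivore = 0, herbivore = 0,
                                     insectivore = 0, omnivore = 0),
    twilight_eta = -20, kappa_activity = 2.5,
    base_visit_rate = 1, seed = 21)
  com <- generate_community(cfg)
  expect_true(all(com$truth$species$p_night > 0.999))
  sim <- simulate_detections(com)
  ev <- independent_events(sim$detections)
  expect_gt(mean(ev$diel_category == "night"), 0.95)
})

test_that("empirical category frequencies converge to the ground truth", {
  cfg <- synth_config(n_sites = 1, site_latitudes = 5, site_longitudes = -60,
                      n_cameras_per_site = 80, n_species = 3,
                      base_visit_rate = 2, photos_per_visit = 1, seed = 14)
  com <- generate_community(cfg)
  sim <- simulate_detections(com)
  # the realised diel category of every visit matches its classification
  cls <- classify_diel(sim$visits$timestamp, 5, -60)
  expect_equal(as.character(cls), sim$visits$category)
  for (s in com$truth$species$species) {
    emp <- mean(sim$visits$category[sim$visits$species == s] == "night")
    n_s <- sum(sim$visits$species == s)
    truth <- com$truth$species$p_night[com$truth$species$species == s]
    expect_lt(abs(emp - truth), 3 * sqrt(truth * (1 - truth) / n_s) + 0.01)
  }
})

test_that("interaction scenarios validate the coupling sign", {
  cfg <- synth_config(coupling_beta = 0.2, seed = 1)
  expect_error(simulate_interaction(cfg, "top_down"), "does not match")
  expect_error(simulate_interaction(cfg, "independent"), "does not match")
  d <- simulate_interaction(cfg, "bottom_up", n_sites = 5)
  expect_equal(nrow(d), 5L * 24L)
  expect_true(all(d$response_count >= 0 & d$predictor_count >= 0))
})

test_that("independent scenario shows near-zero prey-predator correlation", {
  cfg <- synth_config(coupling_beta = 0, seed = 9)
  d <- simulate_interaction(cfg, "independent", n_sites = 200)
  r <- cor(d$predictor_count, d$response_count)
  expect_lt(abs(r), 0.05)
})
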