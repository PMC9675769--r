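# balanced three-category data across a few areas
balanced_diel <- function(n_per = 100, areas = 4) {
  data.frame(
    protected_area = rep(sprintf("PA%d", seq_len(areas)), each = 3 * n_per),
    diel_category = factor(rep(rep(c("day", "twilight", "night"),
                                   each = n_per), areas),
                           levels = c("day", "twilight", "night")),
    log_mass = 0
  )
}

test_that("an intercept-only fit on balanced data predicts equal thirds", {
  fit <- fit_diel_model(balanced_diel(), ~1)
  pp <- predict_probabilities(fit, mass_g = 1000)
  expect_equal(pp$p_day, 1 / 3, tolerance = 1e-6)
  expect_equal(pp$p_night, 1 / 3, tolerance = 1e-6)
  expect_equal(pp$p_twilight, 1 / 3, tolerance = 1e-6)
})

test_that("the candidate set is the five nested guild/mass formulas", {
  cs <- candidate_set()
  expect_length(cs, 5L)
  terms_of <- function(f) attr(terms(f), "term.labels")
  full <- terms_of(cs$mass_by_guild)
  for (f in cs[names(cs) != "mass_by_guild"]) {
    expect_true(all(terms_of(f) %in% full))
  }
})

test_that("model ranking flags the dAIC < 2 supported set and breaks ties", {
  fake <- function(aic, k) list(k = k, logLik = (2 * k - aic) / 2, AIC = aic)
  rk <- select_model(list(a = fake(100, 4), b = fake(101.5, 6),
                          c = fake(110, 8)))
  expect_equal(rk$model, c("a", "b", "c"))
  expect_equal(rk$supported, c(TRUE, TRUE, FALSE))
  tie <- select_model(list(complex = fake(100, 8), simple = fake(100, 4)))
  expect_equal(tie$model[1], "simple")
  expect_true(all(tie$supported))
  expect_error(select_model(list(a = fake(1, 2))), "at least two")
})

test_that("the marginal likelihood at vanishing variance matches the
           fixed-effects multinomial likelihood", {
  com <- generate_community(synth_config(n_species = 10, seed = 31))
  dat <- simulate_diel_counts(com, n_events = 3000, n_sites = 5, seed = 31)
  cells <- camtrapdiel:::.mnl_cells(dat, ~log_mass)
  X <- cells$X; Y <- cells$Y
  ref <- nnet::multinom(Y ~ X - 1, trace = FALSE)
  b <- unname(coef(ref))
  cache <- new.env()
  cache$bn <- numeric(5); cache$bt <- numeric(5)
  nll <- camtrapdiel:::.mnl_negll(c(b[2, ], b[1, ], log(1e-6), log(1e-6)),
                                  X, Y, cells$ai, 5, cache)
  ll_fixed <- sum(Y * log(pmax(fitted(ref), 1e-300)))
  expect_equal(-nll, ll_fixed, tolerance = 1e-4)
})

test_that("predicted probabilities are a softmax: rows sum to one", {
  com <- generate_community(synth_config(n_species = 12, seed = 17))
  dat <- simulate_diel_counts(com, n_events = 4000, n_sites = 6, seed = 17)
  fit <- fit_diel_model(dat, ~ log_mass * guild)
  pp <- predict_probabilities(fit, "herbivore", mass_g = c(100, 1e4, 1e6))
  expect_equal(pp$p_day + pp$p_night + pp$p_twilight, rep(1, 3),
               tolerance = 1e-10)
  expect_true(all(pp$p_night_lo <= pp$p_night & pp$p_night <= pp$p_night_hi))
  # the 1e6 g point lies beyond the simulated mass range
  expect_true(pp$extrapolated[3])
  expect_error(predict_probabilities(fit, "whale", mass_g = 100), "absent")
})

test_that("p_night is monotone in mass when the night slope is positive", {
  com <- generate_community(synth_config(
    guild_proportions = c(carnivore = 0, herbivore = 1, insectivore = 0,
                          omnivore = 0),
    nocturnality_slope_per_guild = c(carnivore = 0, herbivore = 1,
                                     insectivore = 0, omnivore = 0),
    n_species = 20, seed = 23))
  dat <- simulate_diel_counts(com, n_events = 8000, n_sites = 6, seed = 23)
  fit <- fit_diel_model(dat, ~log_mass)
  pp <- predict_probabilities(fit, mass_g = 10^seq(2, 5, length.out = 20))
  expect_true(all(diff(pp$p_night) > 0))
})

test_that("degenerate inputs fail loudly", {
  d <- balanced_diel()
  d$diel_category[d$diel_category == "twilight"] <-
    factor("day", levels = levels(d$diel_category))
  expect_error(fit_diel_model(d, ~1), "empty diel category")
  one_area <- balanced_diel(areas = 1)
  expect_warning(fit1 <- fit_diel_model(one_area, ~1), "single protected area")
  expect_true(fit1$fixed_only)
  pp <- predict_probabilities(fit1, mass_g = 500)
  expect_equal(pp$p_day, 1 / 3, tolerance = 1e-6)
})

test_that("guild-specific mass slopes are recovered on synthetic data", {
  cfg <- synth_config(n_species = 24, seed = 61)
  com <- generate_community(cfg)
  dat <- simulate_diel_counts(com, n_events = 10000, n_sites = 8, seed = 61)
  fit <- fit_diel_model(dat, ~ log_mass * guild)
  truth <- com$truth$slope_per_guild_ln
  co <- fit$coefficients["night", ]
  est <- c(carnivore = co[["log_mass"]],
           herbivore = co[["log_mass"]] + co[["log_mass:guildherbivore"]],
           insectivore = co[["log_mass"]] + co[["log_mass:guildinsectivore"]],
           omnivore = co[["log_mass"]] + co[["log_mass:guildomnivore"]])
  expect_equal(unname(est), unname(truth), tolerance = 0.35)
  expect_true(all(fit$sigma > 0))
  expect_equal(fit$stage, "ML")
})

test_that("worked nocturnality ratios reproduce the published examples", {
  expect_equal(nocturnality_ratio(0.60, 0.13), 4.6)
  expect_equal(nocturnality_ratio(0.81, 0.21), 3.9)
  expect_equal(nocturnality_ratio(0.4, 0.4), 1.0)
  expect_error(nocturnality_ratio(0.5, 0), "0, 1")
})

test_that("coefficient table is tidy: one row per category and term", {
  fit <- fit_diel_model(balanced_diel(), ~1)
  tab <- coef_table(fit)
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$category, c("night", "twilight"))
})
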