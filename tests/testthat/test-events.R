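test_that("independence filter keeps gaps to the last retained event", {
  det <- make_detections(c("2015-03-01 00:00:00", "2015-03-01 00:30:00",
                           "2015-03-01 01:30:00"))
  ev <- independent_events(det)
  expect_equal(nrow(ev), 2L)
  expect_equal(format(ev$timestamp, "%H:%M"), c("00:00", "01:30"))
  # the alternative rule restarts the clock at every photo: one event only
  ev2 <- independent_events(det, rule = "last_photo")
  expect_equal(nrow(ev2), 1L)
})

test_that("independence filter handles single photos, wide gaps, duplicates", {
  expect_equal(nrow(independent_events(make_detections("2015-03-01 10:00:00"))), 1L)
  ev <- independent_events(make_detections(c("2015-03-01 10:00:00",
                                             "2015-03-01 12:00:00")))
  expect_equal(nrow(ev), 2L)
  dup <- independent_events(make_detections(rep("2015-03-01 10:00:00", 3)))
  expect_equal(nrow(dup), 1L)
})

test_that("independence filter is idempotent and never grows the table", {
  set.seed(4)
  for (rep in 1:5) {
    n <- 80
    det <- make_detections(
      as.POSIXct("2015-03-01 00:00:00", tz = "UTC") +
        sort(runif(n, 0, 5 * 86400)),
      species = sample(c("a", "b"), n, replace = TRUE),
      camera = sample(c("C1", "C2"), n, replace = TRUE)
    )
    ev1 <- independent_events(det)
    expect_lte(nrow(ev1), nrow(det))
    ev2 <- independent_events(ev1[names(det)])
    expect_equal(ev2$timestamp, ev1$timestamp)
    # all retained gaps exceed the window within species x camera
    for (g in split(ev1, paste(ev1$species, ev1$camera))) {
      if (nrow(g) > 1) expect_true(all(diff(as.numeric(g$timestamp)) > 3600))
    }
  }
})

test_that("event count equals detection count iff all gaps exceed the window", {
  det <- make_detections(as.POSIXct("2015-03-01 00:00:00", tz = "UTC") +
                           (0:5) * 3700)
  expect_equal(nrow(independent_events(det)), nrow(det))
})

test_that("species filter applies the 75 g and stratum rules", {
  traits <- make_traits(c("tiny", "arb", "ok", "scan"),
                        c(70, 2000, 80, 5000),
                        stratum = c("ground", "arboreal", "ground", "scansorial"))
  det <- make_detections(rep("2015-03-01 10:00:00", 4),
                         species = c("tiny", "arb", "ok", "scan"))
  kept <- filter_species(det, traits)
  expect_setequal(kept$species, c("ok", "scan"))
})

test_that("species without a trait row raise a hard error naming them", {
  det <- make_detections(rep("2015-03-01 10:00:00", 2),
                         species = c("known", "ghost"))
  traits <- make_traits("known", 500)
  expect_error(filter_species(det, traits), "ghost")
})

test_that("guild assignment follows the 80% diet thresholds", {
  expect_equal(assign_guild(0.85, 0.10, 0.05), "carnivore")
  expect_equal(assign_guild(0.10, 0.80, 0.10), "herbivore")
  expect_equal(assign_guild(0.05, 0.10, 0.85), "insectivore")
  expect_equal(assign_guild(0.00, 0.50, 0.50), "omnivore")
  expect_equal(assign_guild(0.79, 0.10, 0.11), "omnivore")
  expect_error(assign_guild(0.9, 0.9, 0.3), "sum")
})

test_that("guild assignment partitions any valid trait table", {
  set.seed(12)
  g <- matrix(rgamma(300, 1), ncol = 3)
  g <- g / rowSums(g)
  out <- assign_guild(g[, 1], g[, 2], g[, 3])
  expect_true(all(out %in% c("carnivore", "herbivore", "insectivore",
                             "omnivore")))
  expect_length(out, 100)
})

test_that("size classes split at 20 kg with a 580 kg exclusion", {
  expect_equal(assign_size_class(c(5000, 20000, 61000, 600000)),
               c("small", "small", "large", "excluded"))
})

test_that("hourly counts give explicit zeros and a full grid", {
  ev <- data.frame(protected_area = "PA1", anchored_hour = 0:23,
                   guild = "herbivore", size_class = "small")
  m <- hourly_counts(ev, guild = "herbivore", size_class = "small")
  expect_equal(dim(m), c(1L, 24L))
  expect_true(all(m == 1))
  expect_warning(m0 <- hourly_counts(ev, guild = "carnivore"), "no events")
  expect_true(all(m0 == 0))
})

test_that("join_traits derives guild, size class and log mass", {
  traits <- make_traits("spA", 25000, vert = 0.9, plant = 0.05, invert = 0.02)
  ev <- data.frame(species = "spA")
  out <- join_traits(ev, traits)
  expect_equal(out$guild, "carnivore")
  expect_equal(out$size_class, "large")
  expect_equal(out$log_mass, log(25000))
})
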