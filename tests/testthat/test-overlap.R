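test_that("circular KDE integrates to one and finds the right mode", {
  set.seed(51)
  x <- rvonmises(5000, pi, 2)
  kde <- fit_circular_kde(x)
  expect_equal(mean(kde$density) * 2 * pi, 1, tolerance = 1e-6)
  expect_true(all(kde$density >= 0))
  mode_at <- kde$grid[which.max(kde$density)]
  expect_lt(abs(mode_at - pi), 0.15)
})

test_that("a uniform circular sample gives a near-flat density", {
  set.seed(52)
  kde <- fit_circular_kde(runif(5000, 0, 2 * pi))
  expect_true(all(abs(kde$density - 1 / (2 * pi)) < 0.15 / (2 * pi)))
})

test_that("KDE rejects degenerate inputs", {
  expect_error(fit_circular_kde(1), "at least 2")
  expect_warning(fit_circular_kde(rep(1.5, 20)), "identical")
})

test_that("overlap of a sample with itself is one", {
  set.seed(53)
  x <- rvonmises(400, 1, 3)
  expect_equal(dhat1(x, x), 1, tolerance = 1e-9)
  expect_equal(dhat4(x, x), 1, tolerance = 1e-9)
})

test_that("overlap estimates are symmetric and rotation invariant", {
  set.seed(54)
  a <- rvonmises(300, 0.5, 3)
  b <- rvonmises(300, 2.5, 2)
  expect_equal(dhat1(a, b), dhat1(b, a), tolerance = 1e-12)
  expect_equal(dhat4(a, b), dhat4(b, a), tolerance = 1e-12)
  for (rot in c(0.7, 2.1, 4.4)) {
    expect_equal(dhat1((a + rot) %% (2 * pi), (b + rot) %% (2 * pi)),
                 dhat1(a, b), tolerance = 0.01)
    expect_equal(dhat4((a + rot) %% (2 * pi), (b + rot) %% (2 * pi)),
                 dhat4(a, b), tolerance = 1e-6)
  }
})

test_that("grid Dhat1 on exact densities matches adaptive quadrature", {
  g <- seq(0, 2 * pi, length.out = 4097)[1:4096]
  f <- dvonmises(g, 0, 4)
  h <- dvonmises(g, pi, 4)
  mine <- camtrapdiel:::.dhat1_from_densities(f, h, g)
  expect_lt(abs(mine - oracle_vm_overlap(0, 4, pi, 4)), 1e-6)
})

test_that("sample-based Dhat estimators approach the quadrature truth", {
  truth <- oracle_vm_overlap(0, 4, pi / 2, 4)  # moderately overlapping pair
  set.seed(55)
  a <- rvonmises(5000, 0, 4)
  b <- rvonmises(5000, pi / 2, 4)
  d1 <- dhat1(a, b)
  d4 <- dhat4(a, b)
  expect_lt(abs(d1 - truth), 0.03)
  expect_lt(abs(d4 - truth), 0.03)
  expect_lt(abs(d1 - d4), 0.05)
})

test_that("estimation error shrinks with sample size", {
  truth <- oracle_vm_overlap(0, 2, pi, 2)
  err_at <- function(n, reps = 6) {
    mean(vapply(seq_len(reps), function(r) {
      set.seed(1000 * n + r)
      abs(overlap_estimate(rvonmises(n, 0, 2), rvonmises(n, pi, 2))$estimate -
            truth)
    }, numeric(1)))
  }
  errs <- vapply(c(50, 500, 5000), err_at, numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.03)
})

test_that("the estimator dispatch follows the per-group sample size", {
  set.seed(56)
  small <- rvonmises(30, 0, 2); big <- rvonmises(200, 1, 2)
  est <- overlap_estimate(small, big)
  expect_equal(est$dhat_type, "Dhat1")
  expect_warning(overlap_estimate(rvonmises(20, 0, 2), big), "25")
  a <- rvonmises(500, 0, 2); b <- rvonmises(500, 1, 2)
  expect_equal(overlap_estimate(a, b)$dhat_type, "Dhat4")
  expect_equal(overlap_estimate(a, b, type = "Dhat1")$dhat_type, "Dhat1")
  expect_error(overlap_estimate(1, b), "n >= 2")
})

test_that("the smoothed bootstrap is reproducible and brackets the estimate", {
  set.seed(57)
  a <- rvonmises(120, 0, 2)
  b <- rvonmises(150, 1.2, 2)
  ci1 <- bootstrap_ci(a, b, n_boot = 200, seed = 7)
  ci2 <- bootstrap_ci(a, b, n_boot = 200, seed = 7)
  expect_identical(ci1[c("ci_lo", "ci_hi")], ci2[c("ci_lo", "ci_hi")])
  expect_lte(ci1$ci_lo, ci1$estimate)
  expect_gte(ci1$ci_hi, ci1$estimate)
  expect_true(ci1$ci_lo >= 0 && ci1$ci_hi <= 1)
})

test_that("identical large samples give a CI concentrated near one", {
  set.seed(58)
  x <- rvonmises(400, 2, 2)
  ci <- bootstrap_ci(x, x, n_boot = 200, seed = 3)
  expect_gte(ci$ci_hi, 0.95)
})

test_that("the randomisation null is reproducible and detects antiphase
           activity", {
  set.seed(59)
  a <- rvonmises(200, 0, 3)
  b <- rvonmises(200, pi, 3)
  n1 <- null_test(a, b, n_reps = 100, seed = 11)
  n2 <- null_test(a, b, n_reps = 100, seed = 11)
  expect_identical(n1$p_null, n2$p_null)
  hits <- 0
  for (r in 1:20) {
    set.seed(600 + r)
    p <- null_test(rvonmises(200, 0, 3), rvonmises(200, pi, 3),
                   n_reps = 100, seed = r)$p_null
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits, 19)
})

test_that("the null test holds its size when both groups share a
           distribution", {
  rej <- 0
  for (r in 1:100) {
    set.seed(700 + r)
    p <- null_test(rvonmises(100, 1, 2), rvonmises(100, 1, 2),
                   n_reps = 200, seed = r)$p_null
    rej <- rej + (p < 0.05)
  }
  expect_lte(rej / 100, 0.12)
})

test_that("the overlap suite reports skipped pairs and valid intervals", {
  set.seed(60)
  n <- 400
  ev <- data.frame(
    protected_area = "PA1",
    guild = sample(c("carnivore", "herbivore"), n, replace = TRUE,
                   prob = c(0.4, 0.6)),
    size_class = sample(c("large", "small"), n, replace = TRUE),
    sun_time_rad = runif(n, 0, 2 * pi), species = "x")
  out <- run_overlap_suite(ev, n_boot = 50, n_null = 50, seed = 2)
  done <- out[!out$skipped, ]
  expect_gt(nrow(done), 0)
  expect_true(all(done$estimate >= 0 & done$estimate <= 1))
  expect_true(all(done$ci_lo >= 0 & done$ci_hi <= 1))
  expect_true(all(out$skipped[out$n_a < 25 | out$n_b < 25]))
})
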