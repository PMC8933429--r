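test_that("synthetic growth data are seed-reproducible and exactly fittable at zero noise", {
  sp <- synthetic_spec("al", 2.8, 0.42, -0.002, noise_sd = 0, n_points = 30,
                       pma_range = c(25, 50), seed = 4)
  d <- generate_growth_dataset(sp)
  cv <- fit_quadratic(d)
  expect_equal(c(cv$a0, cv$a1, cv$a2), c(2.8, 0.42, -0.002), tolerance = 1e-9)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
  # same seed, same bits; different seed differs (noisy mode)
  spn <- synthetic_spec("al", 2.8, 0.42, -0.002, 0.3, 30, c(25, 50), seed = 4)
  expect_identical(generate_growth_dataset(spn), generate_growth_dataset(spn))
  spn2 <- synthetic_spec("al", 2.8, 0.42, -0.002, 0.3, 30, c(25, 50), seed = 5)
  expect_false(identical(generate_growth_dataset(spn)$value,
                         generate_growth_dataset(spn2)$value))
  # the generator must not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_growth_dataset(spn)); after <- runif(1)
  expect_identical(before, after)
  # a spec that forces non-positive values errors out
  bad <- synthetic_spec("lt", 0.5, -0.02, 0, 0, 10, c(25, 50), seed = 1)
  expect_error(generate_growth_dataset(bad), class = "ropzone_error_generation")
})

test_that("noisy fits recover the truth within 3 SE in at least 93% of replicates", {
  truth <- c(2.8, 0.42, -0.002)
  hits <- 0L
  for (s in 1:100) {
    sp <- synthetic_spec("al", truth[1], truth[2], truth[3], noise_sd = 0.3,
                         n_points = 200, pma_range = c(25, 50), seed = s)
    d <- generate_growth_dataset(sp)
    fit <- stats::lm(value ~ pma + I(pma^2),
                     data = data.frame(pma = d$pma, value = d$value))
    est <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    if (all(abs(est - truth) <= 3 * se)) hits <- hits + 1L
  }
  expect_gte(hits, 93L)
})

test_that("mean R^2 of the package fit agrees with the normal-equations oracle", {
  r2_pkg <- numeric(200); r2_or <- numeric(200)
  for (s in 1:200) {
    sp <- synthetic_spec("al", 2.8, 0.42, -0.002, noise_sd = 0.3, n_points = 50,
                         pma_range = c(25, 50), seed = 1000 + s)
    d <- generate_growth_dataset(sp)
    r2_pkg[s] <- fit_quadratic(d)$r_squared
    r2_or[s] <- oracle_quadratic_fit(d$pma, d$value)$r_squared
  }
  expect_equal(r2_pkg, r2_or, tolerance = 1e-8)
  expect_lt(abs(mean(r2_pkg) - mean(r2_or)), 0.05)
})

test_that("builtin fixtures carry the published AL anchors and stay physiological", {
  fx <- builtin_fixtures()
  # source-study multiplicity: 3 K, 3 ACD, 2 P_lens, 2 LT, 8 AL
  counts <- table(vapply(fx, function(cv) cv$parameter, character(1)))
  expect_equal(as.vector(counts[ocular_parameters()]), c(3L, 3L, 2L, 2L, 8L))
  expect_true(all(grepl("^synthetic-", vapply(fx, function(cv) cv$source,
                                              character(1)))))
  # AL candidates at PMA 32 span exactly the reported extremes
  al32 <- evaluate_curves(fx, "al", 32)$value
  expect_equal(min(al32), 14.20, tolerance = 1e-9)
  expect_equal(max(al32), 16.58, tolerance = 1e-9)
  # every candidate combination is a valid eye at every integer PMA 25-50
  for (w in 25:50) {
    r <- enumerate_zone_area_range(grid_from_curves(fx, w))
    expect_equal(r$n_degenerate, 0L)
    expect_equal(r$n_combinations, 288L)
  }
})

test_that("fixture pipeline at PMA 50 brackets the reported Zone I radius range", {
  r50 <- enumerate_zone_area_range(grid_from_curves(builtin_fixtures(), 50))
  expect_gte(r50$radius_min, 6.0)
  expect_lte(r50$radius_max, 8.3)
  expect_lte(r50$radius_min, 6.40)
  expect_gte(r50$radius_max, 7.89)
})

test_that("cohorts are seeded, midpoint-degenerate at zero dispersion, and range-bounded", {
  fx <- builtin_fixtures()
  c0 <- generate_cohort(5, 32, fx, dispersion = 0, seed = 3)
  mid <- midpoint_eye(fx, 32)
  for (e in c0) expect_equal(unclass(e), unclass(mid))
  c1 <- generate_cohort(20, 32, fx, dispersion = 0.2, seed = 3)
  c2 <- generate_cohort(20, 32, fx, dispersion = 0.2, seed = 3)
  expect_identical(c1, c2)
  # areas stay within the enumerated range of the dispersion-extended hull
  grid <- grid_from_curves(fx, 32)
  hull <- lapply(grid$candidates, function(x)
    c(min(x$value) - 2 * 0.2, max(x$value) + 2 * 0.2))
  gext <- parameter_grid(32, hull$p_cornea, hull$acd, hull$p_lens,
                         hull$lt, hull$al)
  rext <- enumerate_zone_area_range(gext)
  for (e in c1) {
    a <- zone_metrics(e)$area
    expect_gte(a, rext$area_min - 1e-9)
    expect_lte(a, rext$area_max + 1e-9)
  }
})
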