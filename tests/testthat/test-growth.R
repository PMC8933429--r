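test_that("noiseless quadratic fits recover coefficients exactly", {
  pma <- 25:40
  d <- growth_dataset("al", pma, 2 + 3 * pma + 0.5 * pma^2, source = "exact")
  cv <- fit_quadratic(d)
  expect_equal(c(cv$a0, cv$a1, cv$a2), c(2, 3, 0.5), tolerance = 1e-9)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
  expect_equal(c(cv$pma_min, cv$pma_max), c(25, 40))
  # a pure line fits with a2 ~ 0 and R^2 = 1
  dl <- growth_dataset("acd", pma, 1 + 0.04 * pma, source = "line")
  cl <- fit_quadratic(dl)
  expect_equal(cl$a2, 0, tolerance = 1e-9)
  expect_equal(cl$r_squared, 1, tolerance = 1e-12)
})

test_that("fit edge cases: rank deficiency and zero variance", {
  d2 <- growth_dataset("al", c(30, 30, 35, 35), c(10, 10.1, 12, 12.2),
                       source = "two-abscissae")
  expect_error(fit_quadratic(d2), class = "ropzone_error_rank_deficient")
  flat <- growth_dataset("lt", c(28, 30, 32, 34), rep(3.5, 4), source = "flat")
  cf <- fit_quadratic(flat)
  expect_true(is.na(cf$r_squared))
})

test_that("lm-based fit matches the normal-equations oracle on noisy data", {
  set.seed(31)
  for (i in 1:20) {
    pma <- sort(runif(50, 25, 50))
    value <- 5 + 0.4 * pma - 0.003 * pma^2 + rnorm(50, 0, 0.3)
    d <- growth_dataset("al", pma, value, source = "noisy")
    cv <- fit_quadratic(d)
    or <- oracle_quadratic_fit(pma, value)
    expect_equal(c(cv$a0, cv$a1, cv$a2), or$coef, tolerance = 1e-8)
    expect_equal(cv$r_squared, or$r_squared, tolerance = 1e-8)
  }
})

test_that("fit is invariant to point order and R^2 to affine PMA rescaling", {
  set.seed(12)
  pma <- sort(runif(40, 25, 50))
  value <- 5 + 0.4 * pma - 0.003 * pma^2 + rnorm(40, 0, 0.2)
  ord <- sample(40)
  c1 <- fit_quadratic(growth_dataset("al", pma, value, source = "a"))
  c2 <- fit_quadratic(growth_dataset("al", pma[ord], value[ord], source = "a"))
  expect_equal(c(c1$a0, c1$a1, c1$a2), c(c2$a0, c2$a1, c2$a2), tolerance = 1e-9)
  c3 <- fit_quadratic(growth_dataset("al", 2 * pma + 5, value, source = "a"))
  expect_equal(c1$r_squared, c3$r_squared, tolerance = 1e-9)
})

test_that("curve evaluation returns per-source candidates with extrapolation flags", {
  cva <- growth_curve("al", 2, 0.3, 0, 25, 50, source = "A")
  cvb <- growth_curve("al", 3, 0.3, 0, 25, 50, source = "B")
  ev <- evaluate_curves(list(cva, cvb), "al", 30)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$source, c("A", "B"))
  expect_equal(ev$value, c(11, 12))
  expect_false(any(ev$extrapolated))
  expect_true(evaluate_curves(list(cva), "al", 55)$extrapolated)
  expect_error(evaluate_curves(list(cva), "acd", 30),
               class = "ropzone_error_lookup")
  # a noiseless fit evaluated at a fitted abscissa returns the original value
  pma <- 25:40
  cv <- fit_quadratic(growth_dataset("acd", pma, 0.5 + 0.05 * pma, source = "x"))
  expect_equal(evaluate_curves(list(cv), "acd", 30)$value, 0.5 + 0.05 * 30,
               tolerance = 1e-9)
})

test_that("keratometric conversion is 337.5/r and an involution", {
  expect_equal(corneal_power_from_curvature(6.75), 50)
  expect_equal(corneal_power_from_curvature(7.50), 45)
  set.seed(2)
  r <- runif(20, 5, 9)
  expect_equal(corneal_curvature_from_power(corneal_power_from_curvature(r)), r,
               tolerance = 1e-12)
  expect_error(corneal_power_from_curvature(0),
               class = "ropzone_error_invalid_input")
})

test_that("Hoffer Q back-calculation matches the stepwise vergence oracle", {
  # emmetropic case: lens power that focuses parallel light on the retina
  p <- lens_power_hoffer_q(al = 16, acd_elp = 4.0, k = 50, refraction = 0)
  expect_equal(p, oracle_lens_power_vergence(16, 4.0, 50, 0), tolerance = 0.01)
  set.seed(9)
  for (i in 1:30) {
    al <- runif(1, 14, 24); elp <- runif(1, 3, 5.5)
    k <- runif(1, 40, 55); rx <- runif(1, -8, 4)
    expect_equal(lens_power_hoffer_q(al, elp, k, rx),
                 oracle_lens_power_vergence(al, elp, k, rx), tolerance = 0.01)
  }
})

test_that("Hoffer Q power moves the right way with refraction and axial length", {
  # more myopic measured refraction implies a stronger crystalline lens
  p_at_rx <- vapply(c(0, -2, -4, -6), function(rx)
    lens_power_hoffer_q(16, 4.0, 50, rx), numeric(1))
  expect_true(all(diff(p_at_rx) > 0))
  # sign check against the vergence oracle
  expect_gt(oracle_lens_power_vergence(16, 4.0, 50, -4),
            oracle_lens_power_vergence(16, 4.0, 50, 0))
  # longer eyes need less lens power, monotonically
  p_at_al <- vapply(c(16, 18, 22, 30, 60), function(al)
    lens_power_hoffer_q(al, 4.0, 50, 0), numeric(1))
  expect_true(all(diff(p_at_al) < 0))
  expect_error(lens_power_hoffer_q(4, 4.0, 50, 0),
               class = "ropzone_error_nonphysical")
})
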