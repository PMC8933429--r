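test_that("degenerate grids: single candidates and AL-extreme selection", {
  g1 <- parameter_grid(32, 53, 2.4, 43, 3.6, 15.5)
  r1 <- enumerate_zone_area_range(g1)
  a <- zone_metrics(ocular_biometry(53, 2.4, 43, 3.6, 15.5))$area
  expect_equal(r1$area_min, a)
  expect_equal(r1$area_max, a)
  expect_equal(r1$n_combinations, 1L)
  expect_equal(r1$n_degenerate, 0L)
  # with two ALs and everything else fixed, extremes sit at the AL extremes
  g2 <- parameter_grid(32, 53, 2.4, 43, 3.6, c(14.20, 16.58))
  r2 <- enumerate_zone_area_range(g2)
  expect_equal(r2$argmin$al, 14.20)
  expect_equal(r2$argmax$al, 16.58)
  expect_lt(r2$area_min, r2$area_max)
})

test_that("enumeration extremes equal the brute-force oracle on 100 random grids", {
  set.seed(77)
  for (i in 1:100) {
    g <- random_grid()
    impl <- enumerate_zone_area_range(g)
    orac <- oracle_range_extremes(g)
    expect_equal(impl$area_min, orac$area_min, tolerance = 1e-12)
    expect_equal(impl$area_max, orac$area_max, tolerance = 1e-12)
    expect_equal(impl$n_degenerate, orac$n_degenerate)
    expect_equal(impl$n_combinations,
                 prod(vapply(g$candidates, nrow, integer(1))))
  }
})

test_that("extremes are invariant to candidate permutation and bound every sample", {
  set.seed(55)
  g <- parameter_grid(32, c(48, 52, 56), c(1.9, 2.3, 2.7), c(38, 44),
                      c(3.4, 3.7), c(13.5, 15.0, 16.5))
  r <- enumerate_zone_area_range(g)
  gp <- parameter_grid(32, c(56, 48, 52), c(2.7, 1.9, 2.3), c(44, 38),
                       c(3.7, 3.4), c(16.5, 13.5, 15.0))
  rp <- enumerate_zone_area_range(gp)
  expect_equal(r$area_min, rp$area_min)
  expect_equal(r$area_max, rp$area_max)
  # any in-grid combination's area lies inside [area_min, area_max]
  for (i in 1:1000) {
    eye <- ocular_biometry(sample(c(48, 52, 56), 1), sample(c(1.9, 2.3, 2.7), 1),
                           sample(c(38, 44), 1), sample(c(3.4, 3.7), 1),
                           sample(c(13.5, 15.0, 16.5), 1))
    a <- zone_metrics(eye)$area
    expect_gte(a, r$area_min - 1e-9)
    expect_lte(a, r$area_max + 1e-9)
  }
})

test_that("an all-degenerate grid raises an empty-range error", {
  g <- parameter_grid(32, 20, 2.4, 5, 3.6, 15)  # weak optics: N' behind retina
  expect_error(enumerate_zone_area_range(g),
               class = "ropzone_error_empty_range")
})

test_that("range_vs_pma tracks the fixture growth and collapses to single enumeration", {
  fx <- builtin_fixtures()
  rr <- range_vs_pma(fx, c(50, 25))  # unordered input comes back sorted
  expect_equal(rr$pma, c(25, 50))
  expect_lt(rr$area_min[1], rr$area_min[2])
  expect_lt(rr$area_max[1], rr$area_max[2])
  expect_true(all(rr$n_degenerate == 0))
  single <- range_vs_pma(fx, 32)
  direct <- enumerate_zone_area_range(grid_from_curves(fx, 32))
  expect_equal(single$area_min, direct$area_min)
  expect_equal(single$area_max, direct$area_max)
})

test_that("AL-extremes analysis has a closed form when other parameters are fixed", {
  other <- list(p_cornea = 53, acd = 2.4, p_lens = 43, lt = 3.6)
  # equal extremes give exactly zero increase
  same <- al_extremes_range(32, 15.5, 15.5, other)
  expect_equal(same$max_percent_increase, 0)
  # single non-AL candidates: increase follows 100*((al_hi-z)^2/(al_lo-z)^2 - 1)
  z <- posterior_nodal_point(ocular_biometry(53, 2.4, 43, 3.6, 15.5))$z_n_image
  ext <- al_extremes_range(32, 14.20, 16.58, other)
  expect_equal(ext$max_percent_increase,
               100 * ((16.58 - z)^2 / (14.20 - z)^2 - 1), tolerance = 1e-9)
  # pooled semantics coincide with paired when nothing else varies
  pooled <- al_extremes_range(32, 14.20, 16.58, other, method = "pooled")
  expect_equal(pooled$max_percent_increase, ext$max_percent_increase,
               tolerance = 1e-9)
})

test_that("paired expansion across PMAs maximizes over shared source combinations", {
  fx <- builtin_fixtures()
  ex <- zone_area_expansion(fx, 31, 38)
  expect_gt(ex$max_percent_increase, 0)
  # paired increase can never exceed the pooled envelope
  pooled <- zone_area_expansion(fx, 31, 38, method = "pooled")
  expect_lte(ex$max_percent_increase, pooled$max_percent_increase)
  # brute-force paired oracle over all 288 source combinations
  g31 <- grid_from_curves(fx, 31); g38 <- grid_from_curves(fx, 38)
  pars <- names(g31$candidates)
  idx <- expand.grid(lapply(g31$candidates, function(x) seq_len(nrow(x))),
                     KEEP.OUT.ATTRS = FALSE)
  best <- -Inf
  for (i in seq_len(nrow(idx))) {
    v31 <- mapply(function(p, j) g31$candidates[[p]]$value[j], pars,
                  as.integer(unlist(idx[i, ])))
    v38 <- mapply(function(p, j) g38$candidates[[p]]$value[j], pars,
                  as.integer(unlist(idx[i, ])))
    a31 <- zone_metrics(do.call(ocular_biometry, as.list(v31)))$area
    a38 <- zone_metrics(do.call(ocular_biometry, as.list(v38)))$area
    best <- max(best, 100 * (a38 - a31) / a31)
  }
  expect_equal(ex$max_percent_increase, best, tolerance = 1e-9)
})
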