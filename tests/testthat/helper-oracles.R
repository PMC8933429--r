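## Independent oracles kept free of the package's internal algebra.

## Equivalent power via explicit 2x2 ray-transfer matrix product
## (reduced-angle convention); the (angle, height) coupling entry is -P_eq.
oracle_equivalent_power <- function(p1, p2, d_mm, n_sep) {
  refr <- function(p) matrix(c(1, -p, 0, 1), 2, 2)
  tran <- function(t_m, n) matrix(c(1, 0, t_m / n, 1), 2, 2)
  m <- refr(p2) %*% tran(d_mm / 1000, n_sep) %*% refr(p1)
  -m[2, 1]
}

## Closed-form normal equations for an OLS quadratic fit.
oracle_quadratic_fit <- function(pma, value) {
  x <- cbind(1, pma, pma^2)
  beta <- solve(t(x) %*% x, t(x) %*% value)
  fitted <- as.numeric(x %*% beta)
  ss_res <- sum((value - fitted)^2)
  ss_tot <- sum((value - mean(value))^2)
  list(coef = as.numeric(beta),
       r_squared = if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot)
}

## Stepwise vergence propagation for the phakic Hoffer Q back-calculation:
## start from the corneal-plane refraction, add corneal power, propagate the
## vergence through aqueous to the lens plane, and take the difference from
## the vergence needed to focus on the retina.
oracle_lens_power_vergence <- function(al, elp, k, refraction = 0,
                                       vertex = 12, t_r = 0.05, n = 1.336) {
  r_c <- refraction / (1 - (vertex / 1000) * refraction)
  v <- r_c + k                              # D, just behind the cornea
  step <- (elp + t_r) / 1000                # m, cornea -> lens plane
  v <- n / (n / v - step)                   # vergence arriving at the lens
  v_needed <- n / ((al - elp - t_r) / 1000) # to focus on the retina
  v_needed - v
}

## Brute-force min/max Zone I area by explicit nested loops.
oracle_range_extremes <- function(grid, indices = refractive_indices(),
                                  config = zone_config()) {
  cands <- grid$candidates
  best_min <- Inf; best_max <- -Inf; n_deg <- 0L
  for (i1 in seq_len(nrow(cands$p_cornea)))
    for (i2 in seq_len(nrow(cands$acd)))
      for (i3 in seq_len(nrow(cands$p_lens)))
        for (i4 in seq_len(nrow(cands$lt)))
          for (i5 in seq_len(nrow(cands$al))) {
            a <- tryCatch(zone_metrics(
              ocular_biometry(cands$p_cornea$value[i1], cands$acd$value[i2],
                              cands$p_lens$value[i3], cands$lt$value[i4],
                              cands$al$value[i5]),
              indices, config)$area,
              error = function(e) NA_real_)
            if (is.na(a)) { n_deg <- n_deg + 1L; next }
            if (a < best_min) best_min <- a
            if (a > best_max) best_max <- a
          }
  list(area_min = best_min, area_max = best_max, n_degenerate = n_deg)
}

## Random physiological biometry (preterm-to-infant ranges).
random_eye <- function() {
  ocular_biometry(p_cornea = runif(1, 40, 60),
                  acd = runif(1, 1.5, 3.2),
                  p_lens = runif(1, 28, 50),
                  lt = runif(1, 3.0, 4.2),
                  al = runif(1, 12, 22))
}

## Random small candidate grid (1-3 candidates per parameter).
random_grid <- function(pma = 32) {
  rc <- function(lo, hi) sort(runif(sample(1:3, 1), lo, hi))
  parameter_grid(pma,
                 p_cornea = rc(40, 60), acd = rc(1.5, 3.2),
                 p_lens = rc(28, 50), lt = rc(3.0, 4.2), al = rc(12, 22))
}
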