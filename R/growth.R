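#' Quadratic growth curve of an ocular parameter against PMA
#'
#' Represents one source study's relationship between a biometric parameter
#' and postmenstrual age (PMA, weeks) as
#' \code{value = a0 + a1 * pma + a2 * pma^2} over a stated PMA domain. The
#' fit quality \code{r_squared} is metadata: curves taken from studies that
#' published their own equations carry the published value (or \code{NA}),
#' and it is never recomputed here.
#'
#' @param parameter One of \code{ocular_parameters()}.
#' @param a0,a1,a2 Polynomial coefficients (value units, units/week,
#'   units/week^2).
#' @param pma_min,pma_max PMA domain in weeks, \code{pma_min <= pma_max}.
#' @param source Free-text study label.
#' @param r_squared Coefficient of determination in [0, 1], or \code{NA} if
#'   unknown/undefined.
#' @return An object of class \code{growth_curve}.
#' @export
growth_curve <- function(parameter, a0, a1, a2, pma_min, pma_max,
                         source = "unknown", r_squared = NA_real_) {
  if (!is.character(parameter) || length(parameter) != 1L ||
      !parameter %in% ocular_parameters())
    rz_error("ropzone_error_invalid_input",
             sprintf("'parameter' must be one of: %s",
                     paste(ocular_parameters(), collapse = ", ")))
  check_number(a0, "a0"); check_number(a1, "a1"); check_number(a2, "a2")
  check_number(pma_min, "pma_min", positive = TRUE)
  check_number(pma_max, "pma_max", positive = TRUE)
  if (pma_min > pma_max)
    rz_error("ropzone_error_invalid_input", "'pma_min' must be <= 'pma_max'")
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    rz_error("ropzone_error_invalid_input", "'r_squared' must lie in [0, 1] or be NA")
  curve <- structure(list(parameter = parameter, a0 = a0, a1 = a1, a2 = a2,
                          pma_min = pma_min, pma_max = pma_max,
                          source = as.character(source),
                          r_squared = r_squared),
                     class = "growth_curve")
  ## a quadratic on an interval attains its minimum at an endpoint or vertex
  wks <- c(pma_min, pma_max)
  if (a2 != 0) {
    vx <- -a1 / (2 * a2)
    if (vx > pma_min && vx < pma_max) wks <- c(wks, vx)
  }
  if (min(predict_growth(curve, wks)$value) <= 0)
    rz_error("ropzone_error_invalid_input",
             sprintf("curve '%s' (%s) predicts non-positive values inside its PMA domain",
                     source, parameter))
  curve
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("Growth curve [%s, %s]: %.6g %+.6g*PMA %+.6g*PMA^2 on [%g, %g] wk; R^2 %s\n",
              x$parameter, x$source, x$a0, x$a1, x$a2, x$pma_min, x$pma_max,
              if (is.na(x$r_squared)) "NA" else sprintf("%.3f", x$r_squared)))
  invisible(x)
}

#' Evaluate one growth curve
#'
#' @param curve A \code{\link{growth_curve}}.
#' @param pma Numeric vector of PMAs, weeks.
#' @return Data frame with columns \code{pma}, \code{value} and
#'   \code{extrapolated} (TRUE where \code{pma} lies outside the curve's
#'   fitted domain).
#' @export
predict_growth <- function(curve, pma) {
  stopifnot(inherits(curve, "growth_curve"))
  if (!is.numeric(pma) || length(pma) == 0 || any(!is.finite(pma)))
    rz_error("ropzone_error_invalid_input", "'pma' must be finite numeric")
  data.frame(pma = pma,
             value = curve$a0 + curve$a1 * pma + curve$a2 * pma^2,
             extrapolated = pma < curve$pma_min | pma > curve$pma_max)
}

#' Growth dataset of (PMA, value) observations
#'
#' @param parameter One of \code{ocular_parameters()}.
#' @param pma Numeric vector of PMAs in weeks (positive).
#' @param value Numeric vector of measurements, same length.
#' @param source Free-text study/source label.
#' @param provenance One of \code{"fixture"}, \code{"synthetic"},
#'   \code{"user"}.
#' @return An object of class \code{growth_dataset}.
#' @export
growth_dataset <- function(parameter, pma, value, source = "unknown",
                           provenance = c("user", "fixture", "synthetic")) {
  provenance <- match.arg(provenance)
  if (!is.character(parameter) || length(parameter) != 1L ||
      !parameter %in% ocular_parameters())
    rz_error("ropzone_error_invalid_input",
             sprintf("'parameter' must be one of: %s",
                     paste(ocular_parameters(), collapse = ", ")))
  if (!is.numeric(pma) || !is.numeric(value) || length(pma) != length(value))
    rz_error("ropzone_error_invalid_input",
             "'pma' and 'value' must be numeric vectors of equal length")
  if (length(pma) < 3)
    rz_error("ropzone_error_invalid_input",
             "at least 3 points are required for quadratic fitting")
  if (any(!is.finite(pma)) || any(!is.finite(value)) || any(pma <= 0))
    rz_error("ropzone_error_invalid_input",
             "PMA values must be finite and positive")
  structure(list(parameter = parameter, pma = as.numeric(pma),
                 value = as.numeric(value), source = as.character(source),
                 provenance = provenance),
            class = "growth_dataset")
}

#' Fit a quadratic growth curve by ordinary least squares
#'
#' Fits \code{value ~ pma + pma^2} with \code{stats::lm}. R-squared is
#' \code{1 - SS_res / SS_tot}; when the response has zero variance the
#' R-squared is undefined and reported as \code{NA}, not 0. The curve's PMA
#' domain is the observed range of the data.
#'
#' @param dataset A \code{\link{growth_dataset}} with at least 3 distinct PMA
#'   values.
#' @return A \code{\link{growth_curve}}.
#' @examples
#' d <- growth_dataset("al", 25:40, 2 + 0.3 * (25:40), source = "demo")
#' fit_quadratic(d)
#' @export
fit_quadratic <- function(dataset) {
  stopifnot(inherits(dataset, "growth_dataset"))
  if (length(unique(dataset$pma)) < 3)
    rz_error("ropzone_error_rank_deficient",
             "quadratic fitting needs at least 3 distinct PMA values")
  df <- data.frame(pma = dataset$pma, value = dataset$value)
  fit <- stats::lm(value ~ pma + I(pma^2), data = df)
  coefs <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((df$value - mean(df$value))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  growth_curve(dataset$parameter,
               a0 = unname(coefs[1]), a1 = unname(coefs[2]), a2 = unname(coefs[3]),
               pma_min = min(dataset$pma), pma_max = max(dataset$pma),
               source = dataset$source, r_squared = r2)
}

#' Per-parameter candidate values at one PMA
#'
#' Evaluates every curve for one parameter at a given PMA, producing the
#' candidate value list (one value per source study) that feeds the
#' combinatorial range model.
#'
#' @param curves A list of \code{\link{growth_curve}} objects (a curve set,
#'   possibly covering several parameters).
#' @param parameter One of \code{ocular_parameters()}.
#' @param pma A single PMA in weeks.
#' @return Data frame with one row per matching curve, in curve-set order:
#'   columns \code{source}, \code{value}, \code{extrapolated}.
#' @export
evaluate_curves <- function(curves, parameter, pma) {
  curves <- as_curve_list(curves)
  check_number(pma, "pma", positive = TRUE)
  sel <- curves[vapply(curves, function(cv) cv$parameter == parameter, logical(1))]
  if (length(sel) == 0)
    rz_error("ropzone_error_lookup",
             sprintf("no growth curve available for parameter '%s'", parameter))
  out <- do.call(rbind, lapply(sel, function(cv) {
    pr <- predict_growth(cv, pma)
    data.frame(source = cv$source, value = pr$value,
               extrapolated = pr$extrapolated, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

as_curve_list <- function(curves) {
  if (inherits(curves, "growth_curve")) curves <- list(curves)
  if (!is.list(curves) || length(curves) == 0 ||
      !all(vapply(curves, inherits, logical(1), "growth_curve")))
    rz_error("ropzone_error_invalid_input",
             "'curves' must be a growth_curve or a non-empty list of them")
  curves
}

#' Keratometric conversion between corneal curvature and power
#'
#' The keratometric convention (index 1.3375) converts a corneal radius of
#' curvature r (mm) to power 337.5 / r (D), and back.
#'
#' @param radius Corneal radius of curvature, mm (> 0, vectorized).
#' @return Corneal power, diopters.
#' @examples
#' corneal_power_from_curvature(6.75)  # 50 D
#' @export
corneal_power_from_curvature <- function(radius) {
  if (!is.numeric(radius) || length(radius) == 0 || any(!is.finite(radius)) ||
      any(radius <= 0))
    rz_error("ropzone_error_invalid_input",
             "'radius' must be positive finite numeric (mm)")
  337.5 / radius
}

#' @rdname corneal_power_from_curvature
#' @param power Corneal power, diopters (> 0, vectorized).
#' @export
corneal_curvature_from_power <- function(power) {
  if (!is.numeric(power) || length(power) == 0 || any(!is.finite(power)) ||
      any(power <= 0))
    rz_error("ropzone_error_invalid_input",
             "'power' must be positive finite numeric (D)")
  337.5 / power
}

#' Vertex correction of a spectacle-plane refraction
#'
#' Moves a refraction measured at the spectacle plane to the corneal plane:
#' \code{R_c = R / (1 - (v/1000) * R)} with vertex distance \code{v} in mm.
#'
#' @param refraction Spectacle-plane refraction, diopters.
#' @param vertex_distance Vertex distance, mm (>= 0). Default 12.
#' @return Corneal-plane refraction, diopters.
#' @export
vertex_correct <- function(refraction, vertex_distance = 12) {
  check_number(refraction, "refraction")
  check_number(vertex_distance, "vertex_distance", nonneg = TRUE)
  denom <- 1 - (vertex_distance / 1000) * refraction
  if (denom <= 0)
    rz_error("ropzone_error_nonphysical",
             "vertex correction denominator is not positive; refraction/vertex combination is non-physical")
  refraction / denom
}

#' Back-calculated phakic lens power (Hoffer Q)
#'
#' Uses the Hoffer Q vergence relation to recover the crystalline lens power
#' that reconciles measured keratometry, anterior-segment geometry, axial
#' length and refraction: the measured effective lens position stands in for
#' the formula's predicted ELP, and the measured refraction (vertex-corrected
#' to the corneal plane) is the target refraction term.
#' \deqn{P = \frac{1000 n}{AL - ELP - t_r} -
#'       \frac{n}{n / (K + R_c) - (ELP + t_r)/1000}}
#' with \code{n = 1.336}, retinal-thickness term \code{t_r = 0.05} mm, and
#' \code{R_c} the corneal-plane refraction.
#'
#' @param al Axial length, mm.
#' @param acd_elp Effective lens position, mm from the corneal vertex; must
#'   be < \code{al}.
#' @param k Keratometric corneal power, diopters (> 0).
#' @param refraction Spectacle-plane refraction, diopters (negative =
#'   myopic). Default 0 (emmetropia).
#' @param vertex_distance Vertex distance for the refraction, mm. Default 12.
#' @param retinal_thickness Retinal thickness term, mm. Default 0.05.
#' @param n_aqueous Index used for the vergence propagation. Default 1.336.
#' @return Lens power, diopters.
#' @export
lens_power_hoffer_q <- function(al, acd_elp, k, refraction = 0,
                                vertex_distance = 12,
                                retinal_thickness = 0.05,
                                n_aqueous = 1.336) {
  check_number(al, "al", positive = TRUE)
  check_number(acd_elp, "acd_elp", positive = TRUE)
  check_number(k, "k", positive = TRUE)
  check_number(refraction, "refraction")
  check_number(retinal_thickness, "retinal_thickness", nonneg = TRUE)
  check_number(n_aqueous, "n_aqueous", positive = TRUE)
  if (al <= acd_elp)
    rz_error("ropzone_error_nonphysical", "'al' must exceed 'acd_elp'")

  r_c <- vertex_correct(refraction, vertex_distance)
  v_cornea <- k + r_c                         # vergence just behind the cornea
  axial_gap <- al - acd_elp - retinal_thickness
  if (axial_gap <= 0)
    rz_error("ropzone_error_nonphysical",
             "lens-to-retina vergence denominator is not positive")
  if (v_cornea == 0)
    rz_error("ropzone_error_nonphysical",
             "corneal-plane vergence is zero; cannot propagate")
  prop_denom <- n_aqueous / v_cornea - (acd_elp + retinal_thickness) / 1000
  if (prop_denom <= 0)
    rz_error("ropzone_error_nonphysical",
             "vergence denominator at the lens plane is not positive")
  1000 * n_aqueous / axial_gap - n_aqueous / prop_denom
}
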