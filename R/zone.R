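#' Zone geometry configuration
#'
#' ICROP Zone I is the circle subtending a 30-degree visual angle from the
#' posterior nodal point; the angle here is the half-angle from the optical
#' axis to the zone edge, so \code{radius = L * tan(angle)} with \code{L} the
#' nodal-point-to-retina distance.
#'
#' @param visual_half_angle Half-angle in degrees, 0 < angle < 90.
#'   Default 30.
#' @return An object of class \code{zone_config}.
#' @export
zone_config <- function(visual_half_angle = 30) {
  check_number(visual_half_angle, "visual_half_angle")
  if (visual_half_angle <= 0 || visual_half_angle >= 90)
    rz_error("ropzone_error_invalid_input",
             "'visual_half_angle' must lie strictly between 0 and 90 degrees")
  structure(list(visual_half_angle = visual_half_angle), class = "zone_config")
}

#' Area of a flat circle
#'
#' Zone area uses the planar approximation pi * r^2; retinal surface
#' curvature is ignored.
#'
#' @param radius Radius in mm (vectorized, all >= 0).
#' @return Area(s) in mm^2.
#' @examples
#' circle_area(7.89)  # about 195.6 mm^2, rounds to 196
#' @export
circle_area <- function(radius) {
  if (!is.numeric(radius) || length(radius) == 0 || any(!is.finite(radius)))
    rz_error("ropzone_error_invalid_input", "'radius' must be finite numeric")
  if (any(radius < 0))
    rz_error("ropzone_error_invalid_input", "'radius' must be >= 0")
  pi * radius^2
}

#' Nerve-to-fovea distance implied by a Zone I radius
#'
#' By the ICROP definition the Zone I radius is twice the distance from the
#' optic nerve to the fovea, so the implied nerve-to-fovea distance is half
#' the radius.
#'
#' @param radius Zone I radius, mm (vectorized, all >= 0).
#' @return Distance(s) in mm.
#' @examples
#' nerve_fovea_distance(6.40)  # 3.20 mm
#' @export
nerve_fovea_distance <- function(radius) {
  if (!is.numeric(radius) || length(radius) == 0 || any(!is.finite(radius)))
    rz_error("ropzone_error_invalid_input", "'radius' must be finite numeric")
  if (any(radius < 0))
    rz_error("ropzone_error_invalid_input", "'radius' must be >= 0")
  radius / 2
}

#' Percent change between two areas
#'
#' @param area_ref Reference area, mm^2 (> 0).
#' @param area_new New area, mm^2.
#' @return Percent change, 100 * (area_new - area_ref) / area_ref.
#' @examples
#' percent_change(100, 172)  # 72
#' @export
percent_change <- function(area_ref, area_new) {
  check_number(area_ref, "area_ref")
  check_number(area_new, "area_new")
  if (area_ref <= 0)
    rz_error("ropzone_error_invalid_input", "'area_ref' must be > 0")
  100 * (area_new - area_ref) / area_ref
}

#' Zone I metrics for one eye
#'
#' Runs the two-element optics on one eye's biometry, subtracts the posterior
#' nodal point position from the axial length to get the nodal-point-to-
#' retina distance \code{L}, and converts it to Zone I geometry:
#' \code{radius = L * tan(half-angle)}, \code{area = pi * radius^2},
#' \code{nerve_fovea_distance = radius / 2}.
#'
#' @param biometry An \code{\link{ocular_biometry}} object.
#' @param indices A \code{\link{refractive_indices}} object.
#' @param config A \code{\link{zone_config}} object.
#' @return An object of class \code{zone_metrics}: list with
#'   \code{nodal_to_retina}, \code{radius}, \code{nerve_fovea_distance} (mm),
#'   \code{area} (mm^2), and the underlying \code{cardinal_points}.
#' @examples
#' eye <- ocular_biometry(53, 2.4, 43, 3.6, 15.5)
#' zone_metrics(eye)  # area about 93 mm^2
#' @export
zone_metrics <- function(biometry, indices = refractive_indices(),
                         config = zone_config()) {
  stopifnot(inherits(config, "zone_config"))
  cp <- posterior_nodal_point(biometry, indices)
  l <- biometry$al - cp$z_n_image          # > 0: enforced by the optics
  radius <- l * tan(config$visual_half_angle * pi / 180)
  structure(list(nodal_to_retina = l,
                 radius = radius,
                 area = circle_area(radius),
                 nerve_fovea_distance = nerve_fovea_distance(radius),
                 cardinal_points = cp),
            class = "zone_metrics")
}

#' @export
print.zone_metrics <- function(x, ...) {
  cat(sprintf("Zone I: radius %.2f mm | area %.0f mm^2 | nerve-fovea %.2f mm | nodal-to-retina %.2f mm\n",
              x$radius, round(x$area), x$nerve_fovea_distance, x$nodal_to_retina))
  invisible(x)
}

#' Single-parameter sensitivity sweep of Zone I area
#'
#' Varies one biometric parameter over a set of values with the remaining
#' four held at the baseline eye, recomputing Zone I metrics for each value.
#' Degenerate combinations (non-convergent optics, nodal point at or behind
#' the retina, impossible geometry) are reported per value rather than
#' aborting the sweep.
#'
#' @param parameter One of \code{"p_cornea"}, \code{"acd"}, \code{"p_lens"},
#'   \code{"lt"}, \code{"al"}.
#' @param values Numeric vector of values to substitute (non-empty); output
#'   rows follow this order.
#' @param baseline An \code{\link{ocular_biometry}} giving the held-constant
#'   parameters.
#' @inheritParams zone_metrics
#' @return A data frame with columns \code{parameter}, \code{value},
#'   \code{radius}, \code{area}, \code{degenerate} (logical) and \code{note}
#'   (failure message for degenerate rows, \code{NA} otherwise).
#' @export
sensitivity_sweep <- function(parameter, values, baseline,
                              indices = refractive_indices(),
                              config = zone_config()) {
  if (!is.character(parameter) || length(parameter) != 1L ||
      !parameter %in% ocular_parameters())
    rz_error("ropzone_error_invalid_input",
             sprintf("'parameter' must be one of: %s",
                     paste(ocular_parameters(), collapse = ", ")))
  if (!is.numeric(values) || length(values) == 0)
    rz_error("ropzone_error_invalid_input", "'values' must be non-empty numeric")
  stopifnot(inherits(baseline, "ocular_biometry"))

  rows <- lapply(values, function(v) {
    args <- baseline[ocular_parameters()]
    args[[parameter]] <- v
    res <- tryCatch({
      zm <- zone_metrics(do.call(ocular_biometry, args), indices, config)
      list(radius = zm$radius, area = zm$area, degenerate = FALSE, note = NA_character_)
    }, ropzone_error = function(e) {
      list(radius = NA_real_, area = NA_real_, degenerate = TRUE,
           note = conditionMessage(e))
    })
    data.frame(parameter = parameter, value = v, radius = res$radius,
               area = res$area, degenerate = res$degenerate, note = res$note,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
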