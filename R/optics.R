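#' Refractive indices of the schematic eye
#'
#' The two-element model uses three media: air in front of the cornea, a
#' combined cornea-plus-aqueous medium between the corneal vertex and the
#' (thin) crystalline lens, and a combined lens-plus-vitreous medium behind
#' it. Defaults are the keratometric convention 1.3375 for cornea/aqueous,
#' 1.4000 for lens/vitreous and 1.0000 for air.
#'
#' @param n_air Refractive index of air (dimensionless, >= 1).
#' @param n_cornea_aqueous Index of the cornea/aqueous medium.
#' @param n_lens_vitreous Index of the lens/vitreous medium.
#' @return An object of class \code{refractive_indices}.
#' @examples
#' refractive_indices()                  # model defaults
#' refractive_indices(n_cornea_aqueous = 4/3, n_lens_vitreous = 4/3)
#' @export
refractive_indices <- function(n_air = 1.0000,
                               n_cornea_aqueous = 1.3375,
                               n_lens_vitreous = 1.4000) {
  check_number(n_air, "n_air")
  check_number(n_cornea_aqueous, "n_cornea_aqueous")
  check_number(n_lens_vitreous, "n_lens_vitreous")
  if (n_air < 1 || n_cornea_aqueous < 1 || n_lens_vitreous < 1)
    rz_error("ropzone_error_invalid_input",
             "all refractive indices must be >= 1.0")
  structure(list(n_air = n_air,
                 n_cornea_aqueous = n_cornea_aqueous,
                 n_lens_vitreous = n_lens_vitreous),
            class = "refractive_indices")
}

#' @export
print.refractive_indices <- function(x, ...) {
  cat("Refractive indices: air", format(x$n_air, nsmall = 4),
      "| cornea/aqueous", format(x$n_cornea_aqueous, nsmall = 4),
      "| lens/vitreous", format(x$n_lens_vitreous, nsmall = 4), "\n")
  invisible(x)
}

#' Single-eye ocular biometry
#'
#' Bundles the five measured parameters of one eye at one time point. The
#' crystalline lens is treated as a symmetric thin element, so its effective
#' axial position is \code{acd + lt/2} from the corneal vertex; that position
#' must lie strictly inside the globe.
#'
#' @param p_cornea Corneal power, diopters (> 0).
#' @param acd Anterior chamber depth, mm (> 0).
#' @param p_lens Crystalline lens power, diopters (>= 0; zero is the
#'   aphakic/reduced-eye limit).
#' @param lt Lens thickness, mm (> 0).
#' @param al Axial length, mm; must exceed \code{acd + lt}.
#' @return An object of class \code{ocular_biometry} with an additional
#'   derived element \code{d} = \code{acd + lt/2} (mm), the cornea-to-lens
#'   separation used by the optics.
#' @examples
#' eye <- ocular_biometry(p_cornea = 53, acd = 2.4, p_lens = 43,
#'                        lt = 3.6, al = 15.5)
#' eye$d  # 4.2 mm
#' @export
ocular_biometry <- function(p_cornea, acd, p_lens, lt, al) {
  check_number(p_cornea, "p_cornea", positive = TRUE)
  check_number(acd, "acd", positive = TRUE)
  check_number(p_lens, "p_lens", nonneg = TRUE)
  check_number(lt, "lt", positive = TRUE)
  check_number(al, "al", positive = TRUE)
  if (al <= acd + lt)
    rz_error("ropzone_error_invalid_geometry",
             sprintf("axial length (%g mm) must exceed acd + lt (%g mm): the lens must lie inside the globe",
                     al, acd + lt))
  d <- acd + lt / 2
  if (d <= 0 || d >= al)
    rz_error("ropzone_error_invalid_geometry",
             "effective lens position acd + lt/2 must lie strictly inside the globe")
  structure(list(p_cornea = p_cornea, acd = acd, p_lens = p_lens,
                 lt = lt, al = al, d = d),
            class = "ocular_biometry")
}

#' @export
print.ocular_biometry <- function(x, ...) {
  cat(sprintf("Ocular biometry: P_cornea %.2f D | ACD %.2f mm | P_lens %.2f D | LT %.2f mm | AL %.2f mm\n",
              x$p_cornea, x$acd, x$p_lens, x$lt, x$al))
  invisible(x)
}

#' Equivalent power of two thin elements
#'
#' Gullstrand combination of two thin refractive elements of powers
#' \code{p1} and \code{p2} (diopters) separated by \code{d} mm of a medium
#' with index \code{n_sep}:
#' \deqn{P_{eq} = P_1 + P_2 - (d/n_{sep}) P_1 P_2,}
#' with the separation converted to meters.
#'
#' @param p1,p2 Element powers, diopters.
#' @param d Separation, mm (>= 0).
#' @param n_sep Index of the separating medium (>= 1).
#' @return Equivalent power, diopters.
#' @examples
#' equivalent_power(60, 0, 4.2, 1.3375)   # 60: a zero second element
#' equivalent_power(53, 43, 4.2, 1.3375)  # about 88.84
#' @export
equivalent_power <- function(p1, p2, d, n_sep) {
  check_number(p1, "p1"); check_number(p2, "p2")
  check_number(n_sep, "n_sep")
  if (!is_number(d) || d < 0)
    rz_error("ropzone_error_invalid_geometry",
             "element separation 'd' must be a single non-negative number (mm)")
  if (n_sep < 1)
    rz_error("ropzone_error_invalid_input", "'n_sep' must be >= 1")
  p1 + p2 - (d / 1000 / n_sep) * p1 * p2
}

#' Ray-transfer matrix of the two-element eye
#'
#' System matrix from the corneal vertex (object space, index \code{n_air})
#' to just behind the lens (image space, index \code{n_lens_vitreous}) in the
#' reduced-angle convention: the ray state is \code{(y, u)} with height
#' \code{y} in meters and reduced angle \code{u = n * theta}. Refraction is
#' \code{u' = u - P y}; transfer over \code{t} meters in index \code{n} is
#' \code{y' = y + (t/n) u}. The matrix is unimodular and its \code{(2,1)}
#' entry equals minus the equivalent power.
#'
#' @inheritParams posterior_nodal_point
#' @return A 2x2 numeric matrix.
#' @export
system_matrix <- function(biometry, indices = refractive_indices()) {
  stopifnot(inherits(biometry, "ocular_biometry"),
            inherits(indices, "refractive_indices"))
  refraction <- function(p) matrix(c(1, -p, 0, 1), 2, 2)
  transfer <- function(t_m, n) matrix(c(1, 0, t_m / n, 1), 2, 2)
  refraction(biometry$p_lens) %*%
    transfer(biometry$d / 1000, indices$n_cornea_aqueous) %*%
    refraction(biometry$p_cornea)
}

#' Cardinal points of the two-element schematic eye
#'
#' Computes the equivalent power and the axial positions (mm from the corneal
#' vertex, positive toward the retina) of the image-side principal point and
#' the posterior nodal point. With separation \code{d = acd + lt/2} (mm) and
#' powers \code{P_c}, \code{P_l}:
#' \deqn{z_{H'} = d (1 - n' P_c / (n_{sep} P_{eq})), \quad
#'       z_{N'} = z_{H'} + 1000 (n' - n) / P_{eq},}
#' where \code{n} and \code{n'} are the object- and image-space indices.
#'
#' @param biometry An \code{\link{ocular_biometry}} object.
#' @param indices A \code{\link{refractive_indices}} object.
#' @return An object of class \code{cardinal_points}: list with \code{p_eq}
#'   (D), \code{z_h_image} and \code{z_n_image} (mm from the corneal vertex).
#' @examples
#' eye <- ocular_biometry(53, 2.4, 43, 3.6, 15.5)
#' posterior_nodal_point(eye)  # z_n_image about 6.08 mm
#' @export
posterior_nodal_point <- function(biometry, indices = refractive_indices()) {
  stopifnot(inherits(biometry, "ocular_biometry"),
            inherits(indices, "refractive_indices"))
  p_eq <- equivalent_power(biometry$p_cornea, biometry$p_lens,
                           biometry$d, indices$n_cornea_aqueous)
  if (p_eq <= 0)
    rz_error("ropzone_error_nonconvergent",
             sprintf("equivalent power is %.3f D; the system must be convergent (P_eq > 0)", p_eq))
  z_h <- biometry$d *
    (1 - indices$n_lens_vitreous * biometry$p_cornea /
       (indices$n_cornea_aqueous * p_eq))
  z_n <- z_h + 1000 * (indices$n_lens_vitreous - indices$n_air) / p_eq
  if (z_n >= biometry$al)
    rz_error("ropzone_error_degenerate_eye",
             sprintf("posterior nodal point (%.3f mm) lies at or behind the retina (AL %.3f mm)",
                     z_n, biometry$al))
  structure(list(p_eq = p_eq, z_h_image = z_h, z_n_image = z_n),
            class = "cardinal_points")
}

#' @export
print.cardinal_points <- function(x, ...) {
  cat(sprintf("Cardinal points: P_eq %.3f D | H' %.4f mm | N' %.4f mm (from corneal vertex)\n",
              x$p_eq, x$z_h_image, x$z_n_image))
  invisible(x)
}

#' Posterior nodal point by paraxial ray tracing
#'
#' Independent verification of \code{\link{posterior_nodal_point}}: traces a
#' paraxial ray surface by surface (refraction \code{u' = u - P y} on the
#' reduced angle \code{u = n theta}; transfer \code{y' = y + t theta}),
#' solves for the entrance height at which the exit angle equals the entrance
#' angle (the defining property of the nodal points), and returns the axial
#' position where that ray crosses the axis in image space. No cardinal-point
#' algebra is reused, so agreement with the closed form is a genuine check.
#'
#' @inheritParams posterior_nodal_point
#' @param angle Entrance ray angle in radians; must satisfy
#'   \code{abs(angle) <= 0.01} for paraxial validity. By linearity the result
#'   does not depend on this value.
#' @return Axial position of the posterior nodal point, mm from the corneal
#'   vertex.
#' @export
ray_trace_nodal_point <- function(biometry, indices = refractive_indices(),
                                  angle = 1e-3) {
  stopifnot(inherits(biometry, "ocular_biometry"),
            inherits(indices, "refractive_indices"))
  check_number(angle, "angle")
  if (angle == 0 || abs(angle) > 0.01)
    rz_error("ropzone_error_invalid_input",
             "'angle' must be nonzero with |angle| <= 0.01 rad for paraxial validity")

  d_m <- biometry$d / 1000
  ## trace from corneal vertex: returns lens-plane height (m) and exit angle (rad)
  trace <- function(y0) {
    u <- indices$n_air * angle                 # reduced angle entering cornea
    u <- u - biometry$p_cornea * y0            # refract at cornea
    y1 <- y0 + d_m * (u / indices$n_cornea_aqueous)  # transfer to lens plane
    u <- u - biometry$p_lens * y1              # refract at lens
    list(y = y1, theta = u / indices$n_lens_vitreous)
  }
  ## exit angle is affine in entrance height; solve theta_exit(y0) == angle
  t0 <- trace(0)
  t1 <- trace(1e-4)
  slope <- (t1$theta - t0$theta) / 1e-4
  ## slope = -P_eq / n_lens_vitreous, so slope >= 0 means P_eq <= 0
  if (slope >= 0)
    rz_error("ropzone_error_nonconvergent",
             "equivalent power is not positive; nodal point undefined")
  y_star <- (angle - t0$theta) / slope
  tr <- trace(y_star)
  ## image-space ray: height tr$y at the lens plane, angle == entrance angle;
  ## axis crossing at z = d - y/theta
  z_n <- biometry$d - 1000 * tr$y / tr$theta
  if (z_n >= biometry$al)
    rz_error("ropzone_error_degenerate_eye",
             sprintf("posterior nodal point (%.3f mm) lies at or behind the retina (AL %.3f mm)",
                     z_n, biometry$al))
  z_n
}
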