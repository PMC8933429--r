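#' Per-parameter candidate grid at one PMA
#'
#' Holds, for each of the five biometric parameters, the list of candidate
#' values (one per source study) to be combined exhaustively by
#' \code{\link{enumerate_zone_area_range}}.
#'
#' @param pma PMA in weeks (single positive number).
#' @param p_cornea,acd,p_lens,lt,al Candidates for each parameter: either a
#'   numeric vector (sources auto-labelled \code{cand1, cand2, ...}) or a
#'   data frame with columns \code{value} and \code{source}.
#' @return An object of class \code{parameter_grid}.
#' @examples
#' parameter_grid(32, p_cornea = c(50, 53), acd = 2.2, p_lens = c(40, 44),
#'                lt = 3.5, al = c(14.20, 16.58))
#' @export
parameter_grid <- function(pma, p_cornea, acd, p_lens, lt, al) {
  check_number(pma, "pma", positive = TRUE)
  cands <- list(p_cornea = p_cornea, acd = acd, p_lens = p_lens,
                lt = lt, al = al)
  cands <- mapply(function(x, nm) {
    if (is.data.frame(x)) {
      if (!all(c("value", "source") %in% names(x)))
        rz_error("ropzone_error_invalid_input",
                 sprintf("candidate data frame for '%s' needs columns 'value' and 'source'", nm))
      x <- data.frame(value = as.numeric(x$value),
                      source = as.character(x$source),
                      stringsAsFactors = FALSE)
    } else if (is.numeric(x) && length(x) >= 1) {
      x <- data.frame(value = as.numeric(x),
                      source = paste0("cand", seq_along(x)),
                      stringsAsFactors = FALSE)
    } else {
      rz_error("ropzone_error_invalid_input",
               sprintf("candidates for '%s' must be numeric or a value/source data frame", nm))
    }
    if (nrow(x) == 0 || any(!is.finite(x$value)) || any(x$value <= 0))
      rz_error("ropzone_error_invalid_input",
               sprintf("candidates for '%s' must be non-empty, finite and positive", nm))
    x
  }, cands, names(cands), SIMPLIFY = FALSE)
  structure(list(pma = pma, candidates = cands), class = "parameter_grid")
}

#' Grid of candidate values from a curve set at one PMA
#'
#' Evaluates every curve of a set at the given PMA and assembles the
#' resulting per-parameter candidate lists into a
#' \code{\link{parameter_grid}}.
#'
#' @param curves A list of \code{\link{growth_curve}} objects covering all
#'   five parameters.
#' @param pma A single PMA in weeks.
#' @return A \code{\link{parameter_grid}}.
#' @export
grid_from_curves <- function(curves, pma) {
  curves <- as_curve_list(curves)
  cand <- lapply(ocular_parameters(), function(p) {
    ev <- evaluate_curves(curves, p, pma)
    ev[, c("value", "source")]
  })
  names(cand) <- ocular_parameters()
  do.call(parameter_grid, c(list(pma = pma), cand))
}

#' Exhaustive min/max Zone I area over a candidate grid
#'
#' Evaluates the schematic-eye model for every combination in the Cartesian
#' product of the per-parameter candidate lists and reports the smallest and
#' largest Zone I areas together with the biometry combinations achieving
#' them. Combinations on which the optics degenerate (non-convergent system,
#' nodal point at or behind the retina, lens outside the globe) are counted
#' in \code{n_degenerate} and excluded from the extremes. Enumeration order
#' is deterministic (first parameter varies fastest) and ties are broken by
#' the first combination encountered.
#'
#' @param grid A \code{\link{parameter_grid}}.
#' @inheritParams zone_metrics
#' @return An object of class \code{zone_area_range}: list with \code{pma},
#'   \code{area_min}, \code{area_max}, \code{radius_min}, \code{radius_max}
#'   (mm), \code{argmin} and \code{argmax} (one-row data frames of the
#'   achieving combination: values and sources), \code{n_combinations} and
#'   \code{n_degenerate}.
#' @export
enumerate_zone_area_range <- function(grid, indices = refractive_indices(),
                                      config = zone_config()) {
  stopifnot(inherits(grid, "parameter_grid"))
  cands <- grid$candidates
  idx <- expand.grid(lapply(cands, function(x) seq_len(nrow(x))),
                     KEEP.OUT.ATTRS = FALSE)
  n_comb <- nrow(idx)
  areas <- numeric(n_comb)
  ok <- logical(n_comb)
  for (i in seq_len(n_comb)) {
    vals <- mapply(function(p, j) cands[[p]]$value[j],
                   names(cands), as.integer(unlist(idx[i, ])))
    res <- tryCatch(
      zone_metrics(do.call(ocular_biometry, as.list(vals)), indices, config),
      ropzone_error = function(e) NULL)
    if (is.null(res)) {
      areas[i] <- NA_real_
    } else {
      areas[i] <- res$area
      ok[i] <- TRUE
    }
  }
  if (!any(ok))
    rz_error("ropzone_error_empty_range",
             "every candidate combination is degenerate; no Zone I range can be computed")

  combo_row <- function(i) {
    row <- list()
    for (p in names(cands)) {
      j <- idx[i, p]
      row[[p]] <- cands[[p]]$value[j]
      row[[paste0(p, "_source")]] <- cands[[p]]$source[j]
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  }
  i_min <- which(ok)[which.min(areas[ok])]
  i_max <- which(ok)[which.max(areas[ok])]
  structure(list(pma = grid$pma,
                 area_min = areas[i_min], area_max = areas[i_max],
                 radius_min = sqrt(areas[i_min] / pi),
                 radius_max = sqrt(areas[i_max] / pi),
                 argmin = combo_row(i_min), argmax = combo_row(i_max),
                 n_combinations = n_comb,
                 n_degenerate = sum(!ok)),
            class = "zone_area_range")
}

#' @export
print.zone_area_range <- function(x, ...) {
  cat(sprintf("Zone I area range at PMA %g wk: %.1f to %.1f mm^2 (radius %.2f to %.2f mm; %d combinations, %d degenerate)\n",
              x$pma, x$area_min, x$area_max, x$radius_min, x$radius_max,
              x$n_combinations, x$n_degenerate))
  invisible(x)
}

#' @export
as.data.frame.zone_area_range <- function(x, ...) {
  data.frame(pma = x$pma, area_min = x$area_min, area_max = x$area_max,
             radius_min = x$radius_min, radius_max = x$radius_max,
             n_combinations = x$n_combinations, n_degenerate = x$n_degenerate)
}

#' Zone I area ranges across a PMA sweep
#'
#' Evaluates a curve set at each requested PMA and enumerates the Zone I
#' area range there.
#'
#' @param curves A curve set covering all five parameters.
#' @param pma_list Numeric vector of PMAs, weeks; results are ordered by
#'   increasing PMA.
#' @inheritParams zone_metrics
#' @return A data frame with one row per PMA (columns as in
#'   \code{as.data.frame.zone_area_range}); the full
#'   \code{zone_area_range} objects are attached as attribute
#'   \code{"details"}.
#' @examples
#' rng <- range_vs_pma(builtin_fixtures(), c(32, 40))
#' rng[, c("pma", "area_min", "area_max")]
#' @export
range_vs_pma <- function(curves, pma_list, indices = refractive_indices(),
                         config = zone_config()) {
  if (!is.numeric(pma_list) || length(pma_list) == 0)
    rz_error("ropzone_error_invalid_input", "'pma_list' must be non-empty numeric")
  pma_list <- sort(pma_list)
  details <- lapply(pma_list, function(w)
    enumerate_zone_area_range(grid_from_curves(curves, w), indices, config))
  out <- do.call(rbind, lapply(details, as.data.frame))
  rownames(out) <- NULL
  attr(out, "details") <- details
  out
}

#' Zone I area ranges at two axial-length extremes
#'
#' Fixes the axial length at each of two observed extremes, enumerates the
#' other four parameters over their candidate values, and reports both area
#' ranges plus the maximum percent increase in area from the short to the
#' long eye.
#'
#' Two interpretations of the maximum increase are provided:
#' \describe{
#'   \item{\code{"paired"}}{(default) the non-AL parameters are held
#'     identical across the pair; the increase is maximized over those
#'     shared combinations.}
#'   \item{\code{"pooled"}}{the increase between any pair of combinations:
#'     \code{area_max} at \code{al_max} versus \code{area_min} at
#'     \code{al_min}.}
#' }
#'
#' @param pma PMA in weeks (label carried through to the outputs).
#' @param al_min,al_max The two axial lengths, mm, \code{al_min < al_max}.
#' @param other Candidates for the other four parameters: a named list with
#'   elements \code{p_cornea}, \code{acd}, \code{p_lens}, \code{lt} (numeric
#'   vectors or value/source data frames), or a curve set from which they
#'   are evaluated at \code{pma}.
#' @param method Percent-increase semantics; see Details.
#' @inheritParams zone_metrics
#' @return A list with \code{range_low} and \code{range_high} (the
#'   \code{zone_area_range} at each AL), \code{max_percent_increase}, and
#'   \code{method}.
#' @export
al_extremes_range <- function(pma, al_min, al_max, other,
                              indices = refractive_indices(),
                              config = zone_config(),
                              method = c("paired", "pooled")) {
  method <- match.arg(method)
  check_number(al_min, "al_min", positive = TRUE)
  check_number(al_max, "al_max", positive = TRUE)
  if (al_min > al_max)
    rz_error("ropzone_error_invalid_input", "'al_min' must be <= 'al_max'")
  if (is.list(other) && all(vapply(other, inherits, logical(1), "growth_curve"))) {
    other <- lapply(setdiff(ocular_parameters(), "al"), function(p)
      evaluate_curves(other, p, pma)[, c("value", "source")])
    names(other) <- setdiff(ocular_parameters(), "al")
  }
  if (!all(setdiff(ocular_parameters(), "al") %in% names(other)))
    rz_error("ropzone_error_invalid_input",
             "'other' must supply candidates for p_cornea, acd, p_lens and lt")

  grid_at <- function(al) do.call(parameter_grid,
                                  c(list(pma = pma),
                                    other[setdiff(ocular_parameters(), "al")],
                                    list(al = al)))
  lo <- enumerate_zone_area_range(grid_at(al_min), indices, config)
  hi <- enumerate_zone_area_range(grid_at(al_max), indices, config)

  if (method == "pooled") {
    pct <- percent_change(lo$area_min, hi$area_max)
  } else {
    ## paired: same non-AL combination on both sides; enumeration order is
    ## identical for the two grids, so combinations align index by index
    pair_areas <- function(al) {
      g <- grid_at(al)
      cands <- g$candidates
      idx <- expand.grid(lapply(cands, function(x) seq_len(nrow(x))),
                         KEEP.OUT.ATTRS = FALSE)
      vapply(seq_len(nrow(idx)), function(i) {
        vals <- mapply(function(p, j) cands[[p]]$value[j],
                       names(cands), as.integer(unlist(idx[i, ])))
        tryCatch(zone_metrics(do.call(ocular_biometry, as.list(vals)),
                              indices, config)$area,
                 ropzone_error = function(e) NA_real_)
      }, numeric(1))
    }
    a_lo <- pair_areas(al_min)
    a_hi <- pair_areas(al_max)
    valid <- !is.na(a_lo) & !is.na(a_hi)
    if (!any(valid))
      rz_error("ropzone_error_empty_range",
               "no candidate combination is non-degenerate at both AL extremes")
    pct <- max(100 * (a_hi[valid] - a_lo[valid]) / a_lo[valid])
  }
  list(range_low = lo, range_high = hi,
       max_percent_increase = pct, method = method)
}

#' Maximum Zone I area expansion between two PMAs
#'
#' Quantifies how much the absolute Zone I area can grow from one PMA to
#' another under a curve set. With \code{method = "paired"} (default) the
#' same source combination is evaluated at both ages and the percent
#' increase is maximized over combinations; with \code{method = "pooled"}
#' the extreme areas are compared (\code{area_max} at \code{pma_to} versus
#' \code{area_min} at \code{pma_from}).
#'
#' @param curves A curve set covering all five parameters.
#' @param pma_from,pma_to The two PMAs, weeks.
#' @inheritParams al_extremes_range
#' @return A list with the two \code{zone_area_range} objects,
#'   \code{max_percent_increase}, and \code{method}.
#' @export
zone_area_expansion <- function(curves, pma_from, pma_to,
                                indices = refractive_indices(),
                                config = zone_config(),
                                method = c("paired", "pooled")) {
  method <- match.arg(method)
  check_number(pma_from, "pma_from", positive = TRUE)
  check_number(pma_to, "pma_to", positive = TRUE)
  g_from <- grid_from_curves(curves, pma_from)
  g_to <- grid_from_curves(curves, pma_to)
  r_from <- enumerate_zone_area_range(g_from, indices, config)
  r_to <- enumerate_zone_area_range(g_to, indices, config)
  if (method == "pooled") {
    pct <- percent_change(r_from$area_min, r_to$area_max)
  } else {
    areas_at <- function(g) {
      cands <- g$candidates
      idx <- expand.grid(lapply(cands, function(x) seq_len(nrow(x))),
                         KEEP.OUT.ATTRS = FALSE)
      vapply(seq_len(nrow(idx)), function(i) {
        vals <- mapply(function(p, j) cands[[p]]$value[j],
                       names(cands), as.integer(unlist(idx[i, ])))
        tryCatch(zone_metrics(do.call(ocular_biometry, as.list(vals)),
                              indices, config)$area,
                 ropzone_error = function(e) NA_real_)
      }, numeric(1))
    }
    a_from <- areas_at(g_from)
    a_to <- areas_at(g_to)
    valid <- !is.na(a_from) & !is.na(a_to)
    if (!any(valid))
      rz_error("ropzone_error_empty_range",
               "no source combination is non-degenerate at both PMAs")
    pct <- max(100 * (a_to[valid] - a_from[valid]) / a_from[valid])
  }
  list(range_from = r_from, range_to = r_to,
       max_percent_increase = pct, method = method)
}
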