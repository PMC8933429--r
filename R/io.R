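## CSV dialects. Units are fixed per column (D, mm, weeks) and validated by
## header, never inferred.

CURVES_HEADER <- c("parameter", "a0", "a1", "a2", "pma_min", "pma_max",
                   "source", "r2")
POINTS_HEADER <- c("parameter", "pma_weeks", "value", "source")
BIOMETRY_HEADER <- c("p_cornea", "acd", "p_lens", "lt", "al")

check_header <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    rz_error("ropzone_error_csv",
             sprintf("'%s' is missing required column(s): %s",
                     path, paste(missing, collapse = ", ")))
  invisible(df)
}

#' Read and write growth-curve coefficient CSVs
#'
#' The \code{curves.csv} dialect has columns \code{parameter, a0, a1, a2,
#' pma_min, pma_max, source, r2} (RFC 4180, UTF-8, dot decimal; r2 may be
#' empty for unknown). Supplying externally fitted coefficient tables in
#' this dialect -- e.g. published parameter-vs-PMA equations -- switches the
#' whole pipeline from the built-in synthetic fixtures to those curves.
#'
#' @param path CSV file path.
#' @return \code{read_curves_csv}: a list of \code{\link{growth_curve}}
#'   objects in file order.
#' @export
read_curves_csv <- function(path) {
  if (!file.exists(path))
    rz_error("ropzone_error_csv", sprintf("file not found: '%s'", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_header(df, CURVES_HEADER, path)
  lapply(seq_len(nrow(df)), function(i) {
    r2 <- df$r2[i]
    growth_curve(df$parameter[i], df$a0[i], df$a1[i], df$a2[i],
                 df$pma_min[i], df$pma_max[i], df$source[i],
                 r_squared = if (is.na(r2) || identical(r2, "")) NA_real_
                             else as.numeric(r2))
  })
}

#' @rdname read_curves_csv
#' @param curves A curve set (list of \code{\link{growth_curve}}).
#' @return \code{write_curves_csv}: the path, invisibly.
#' @export
write_curves_csv <- function(curves, path) {
  curves <- as_curve_list(curves)
  df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(parameter = cv$parameter, a0 = cv$a0, a1 = cv$a1, a2 = cv$a2,
               pma_min = cv$pma_min, pma_max = cv$pma_max, source = cv$source,
               r2 = cv$r_squared, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read and write growth-observation CSVs
#'
#' The \code{points.csv} dialect has columns \code{parameter, pma_weeks,
#' value, source}; one measurement per row. Units: weeks for
#' \code{pma_weeks}; D for powers, mm for lengths in \code{value}.
#'
#' @param path CSV file path.
#' @return \code{read_points_csv}: a list of \code{\link{growth_dataset}}
#'   objects, one per (parameter, source) group, in first-appearance order.
#' @export
read_points_csv <- function(path) {
  if (!file.exists(path))
    rz_error("ropzone_error_csv", sprintf("file not found: '%s'", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_header(df, POINTS_HEADER, path)
  key <- paste(df$parameter, df$source, sep = "\r")
  lapply(unique(key), function(k) {
    sub <- df[key == k, ]
    growth_dataset(sub$parameter[1], sub$pma_weeks, sub$value,
                   source = sub$source[1], provenance = "user")
  })
}

#' @rdname read_points_csv
#' @param datasets A \code{\link{growth_dataset}} or list of them.
#' @return \code{write_points_csv}: the path, invisibly.
#' @export
write_points_csv <- function(datasets, path) {
  if (inherits(datasets, "growth_dataset")) datasets <- list(datasets)
  df <- do.call(rbind, lapply(datasets, function(d)
    data.frame(parameter = d$parameter, pma_weeks = d$pma, value = d$value,
               source = d$source, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read and write single-eye biometry CSVs
#'
#' The biometry dialect has columns \code{p_cornea, acd, p_lens, lt, al}
#' (D, mm, D, mm, mm), one eye per row; extra columns (e.g. an id) are
#' carried through unchanged by \code{\link{run_area}}.
#'
#' @param path CSV file path.
#' @return \code{read_biometry_csv}: a list of
#'   \code{\link{ocular_biometry}} objects; row construction errors are
#'   re-raised with the offending row index.
#' @export
read_biometry_csv <- function(path) {
  if (!file.exists(path))
    rz_error("ropzone_error_csv", sprintf("file not found: '%s'", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_header(df, BIOMETRY_HEADER, path)
  lapply(seq_len(nrow(df)), function(i) {
    tryCatch(ocular_biometry(df$p_cornea[i], df$acd[i], df$p_lens[i],
                             df$lt[i], df$al[i]),
             ropzone_error = function(e)
               rz_error(class(e)[1],
                        sprintf("row %d of '%s': %s", i, path,
                                conditionMessage(e))))
  })
}

#' @rdname read_biometry_csv
#' @param eyes An \code{\link{ocular_biometry}} or list of them.
#' @return \code{write_biometry_csv}: the path, invisibly.
#' @export
write_biometry_csv <- function(eyes, path) {
  if (inherits(eyes, "ocular_biometry")) eyes <- list(eyes)
  df <- do.call(rbind, lapply(eyes, function(e)
    data.frame(p_cornea = e$p_cornea, acd = e$acd, p_lens = e$p_lens,
               lt = e$lt, al = e$al)))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
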