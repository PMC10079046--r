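#' Mortality observation schema
#'
#' Every estimation stage consumes a common long-format observation table:
#' one row per data point with
#' `source` (`DRS`, `SBH_MAC`, `SBH_MAP`, `CBH`), `province`,
#' `year` (reference year; fractional years allowed for birth-history
#' estimates), `measure` (`U5MR` or `NMR`), `value` (deaths per 1,000 live
#' births), `design_variance` (sampling variance on the log scale) and
#' `completeness_adjustable` (`TRUE` only for registration data, whose values
#' the models correct for under-registration). An optional `completeness`
#' column carries the true completeness in synthetic data.
#'
#' `validate_observations()` checks the schema and value ranges and reports
#' offending row numbers; the read/write pair round-trips the table as CSV.
#'
#' @param obs an observation tibble.
#' @param horizon optional inclusive year range observations must fall into.
#' @return `obs`, invisibly, after validation.
#' @export
validate_observations <- function(obs, horizon = NULL) {
  req <- c("source", "province", "year", "measure", "value", "design_variance")
  miss <- setdiff(req, names(obs))
  if (length(miss)) abort(sprintf("observations lack columns: %s", paste(miss, collapse = ", ")))
  bad <- which(!is.finite(obs$value) | obs$value < 0 | obs$value >= 1000)
  if (length(bad)) {
    abort(sprintf("observation values outside [0, 1000) at rows: %s",
                  paste(head(bad, 10), collapse = ", ")))
  }
  bad_v <- which(!is.finite(obs$design_variance) | obs$design_variance < 0)
  if (length(bad_v)) {
    abort(sprintf("negative or missing design_variance at rows: %s",
                  paste(head(bad_v, 10), collapse = ", ")))
  }
  if (!is.null(horizon)) {
    bad_y <- which(obs$year < horizon[1] - 15 | obs$year > horizon[2] + 1)
    if (length(bad_y)) {
      abort(sprintf("reference years far outside the horizon at rows: %s",
                    paste(head(bad_y, 10), collapse = ", ")))
    }
  }
  bad_m <- which(!obs$measure %in% c("U5MR", "NMR"))
  if (length(bad_m)) {
    abort(sprintf("unknown measure at rows: %s", paste(head(bad_m, 10), collapse = ", ")))
  }
  invisible(obs)
}

#' @rdname validate_observations
#' @param path CSV path.
#' @export
write_observations <- function(obs, path) {
  validate_observations(obs)
  write.csv(obs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname validate_observations
#' @export
read_observations <- function(path, horizon = NULL) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!"completeness_adjustable" %in% names(df)) df$completeness_adjustable <- df$source == "DRS"
  if (!"completeness" %in% names(df)) df$completeness <- NA_real_
  validate_observations(df, horizon = horizon)
  df
}
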