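#' Data-quality gate for candidate data sources
#'
#' A dataset enters the analysis only if (a) the missing-value fraction of its
#' key variables does not exceed the cutoff and (b) its boys-to-girls sex
#' ratio is plausible. Both bounds are inclusive: a dataset exactly at the
#' missing cutoff or at a sex-ratio bound is accepted.
#'
#' @param dataset_summary a list or one-row data frame with numeric
#'   `missing_fraction` (in `[0, 1]`) and `sex_ratio`.
#' @param missing_cutoff missing-value cutoff, configurable in `[0.05, 0.10]`.
#' @param sex_ratio_bounds plausible inclusive sex-ratio interval.
#' @return A one-row tibble: `accept` (logical) and `reason` (`NA` when
#'   accepted, otherwise the violated rule(s)).
#' @export
#' @examples
#' qc_gate(list(missing_fraction = 0.28, sex_ratio = 1.08))
qc_gate <- function(dataset_summary, missing_cutoff = 0.10,
                    sex_ratio_bounds = c(1.00, 1.06)) {
  s <- as.list(dataset_summary)
  for (nm in c("missing_fraction", "sex_ratio")) {
    if (is.null(s[[nm]]) || !is.numeric(s[[nm]]) || length(s[[nm]]) != 1 || is.na(s[[nm]])) {
      abort(sprintf("`dataset_summary$%s` is missing or not a number; refusing to silently accept", nm))
    }
  }
  if (missing_cutoff < 0.05 || missing_cutoff > 0.10) {
    abort("`missing_cutoff` must lie in [0.05, 0.10]")
  }
  reasons <- character()
  if (s$missing_fraction > missing_cutoff) {
    reasons <- c(reasons, sprintf("missing_fraction %.3g exceeds cutoff %.3g",
                                  s$missing_fraction, missing_cutoff))
  }
  if (s$sex_ratio < sex_ratio_bounds[1] || s$sex_ratio > sex_ratio_bounds[2]) {
    reasons <- c(reasons, sprintf("sex_ratio %.3g outside plausible [%.2f, %.2f]",
                                  s$sex_ratio, sex_ratio_bounds[1], sex_ratio_bounds[2]))
  }
  tibble(accept = length(reasons) == 0,
         reason = if (length(reasons)) paste(reasons, collapse = "; ") else NA_character_)
}

#' Direct U5MR from complete birth histories
#'
#' The occurrence/exposure rate for a calendar year is the weighted number of
#' under-5 deaths in that year divided by the weighted person-years children
#' under 5 lived in it. The rate is converted to a probability-type 5q0 via the
#' constant-hazard identity `5q0 = 1000 (1 - exp(-5 m))`; set
#' `conversion = "none"` to report the raw `1000 * 5 m` instead.
#'
#' @param records a tibble of birth records: `birth_time` (fractional calendar
#'   year), `alive`, `age_at_death_months` (`NA` iff alive), `weight`;
#'   optionally a single-valued `province`.
#' @param calendar_year the calendar year estimated.
#' @param conversion rate-to-probability conversion.
#' @return A one-row observation tibble (see [validate_observations()]);
#'   `design_variance` is the weighted-Poisson `1 / deaths` (with a +0.5
#'   continuity correction when no deaths are observed).
#' @export
cbh_u5mr <- function(records, calendar_year,
                     conversion = c("constant-hazard", "none")) {
  conversion <- match.arg(conversion)
  req <- c("birth_time", "alive", "age_at_death_months", "weight")
  miss <- setdiff(req, names(records))
  if (length(miss)) abort(sprintf("records lack columns: %s", paste(miss, collapse = ", ")))
  if (any(!records$alive & is.na(records$age_at_death_months)) ||
      any(records$alive & !is.na(records$age_at_death_months))) {
    abort("`age_at_death_months` must be present iff the child died")
  }
  province <- NA_character_
  if ("province" %in% names(records)) {
    pv <- unique(records$province)
    if (length(pv) > 1) abort("records span several provinces; estimate one province at a time")
    province <- pv
  }
  y0 <- calendar_year
  bt <- records$birth_time
  dead <- !records$alive
  death_time <- ifelse(dead, bt + (records$age_at_death_months + 0.5) / 12, Inf)
  risk_end <- pmin(bt + 5, death_time)
  exposure <- pmax(0, pmin(risk_end, y0 + 1) - pmax(bt, y0))
  death_in_year <- dead & death_time >= y0 & death_time < y0 + 1 &
    records$age_at_death_months < 60
  w <- records$weight
  E <- sum(w * exposure)
  if (E <= 0) abort("no person-time of under-5 exposure in that calendar year")
  D <- sum(w * death_in_year)
  D_eff <- if (D == 0) 0.5 else D
  m <- D / E
  value <- switch(conversion,
    `constant-hazard` = 1000 * (1 - exp(-5 * m)),
    none = 1000 * 5 * m
  )
  tibble(source = "CBH", province = province, year = y0 + 0.5,
         measure = "U5MR", value = value, design_variance = 1 / D_eff,
         completeness_adjustable = FALSE, completeness = NA_real_)
}

#' Coefficient sets for indirect summary-birth-history estimation
#'
#' Indirect estimators convert children-dead / children-ever-born ratios into
#' time-located 5q0 estimates through age-group-specific multipliers and time
#' offsets. Three sets ship with the package:
#'
#' * `brass_coefs()` — classical Brass-style multipliers and reference-time
#'   offsets for the seven maternal age groups. These are illustrative default
#'   values in the spirit of the published model-life-table regressions; a
#'   production analysis should plug in coefficients matched to its fertility
#'   and mortality pattern via `read_coefs()`.
#' * `identity_coefs()` — unit multipliers (estimate equals `1000 cd/ceb`)
#'   with the standard offsets; used for testing the mechanics.
#' * `calibrated_sbh_coefs()` — multipliers and offsets derived by numerical
#'   integration from the same fertility/exposure assumptions the synthetic
#'   generator uses, so indirect estimates on generated data are consistent
#'   with the generating truth (the analogue of deriving coefficients from a
#'   model life table).
#'
#' @return A tibble `age_group`, `multiplier`, `time_offset` (years before the
#'   survey).
#' @export
brass_coefs <- function() {
  tibble(age_group = sbh_age_groups()$age_group,
         multiplier = c(1.30, 1.17, 1.08, 1.03, 1.01, 1.00, 0.99),
         time_offset = c(1.2, 2.6, 4.2, 6.0, 8.0, 10.2, 12.7))
}

#' @rdname brass_coefs
#' @export
identity_coefs <- function() {
  coefs <- brass_coefs()
  coefs$multiplier <- 1
  coefs
}

#' @rdname brass_coefs
#' @param exponent exponent of the cumulative under-5 risk-fraction curve
#'   (must match the generator's).
#' @param grid_n integration grid size.
#' @export
calibrated_sbh_coefs <- function(exponent = 0.4, grid_n = 400) {
  groups <- sbh_age_groups()
  res <- map(seq_len(nrow(groups)), function(i) {
    u <- seq(groups$lower[i] + 0.001, groups$lower[i] + 5, length.out = grid_n)
    eg <- numeric(grid_n); ea <- numeric(grid_n)
    for (j in seq_len(grid_n)) {
      span <- max(u[j] - 15, 0.25)
      a <- seq(0, span, length.out = grid_n)
      g <- u5_cum_frac(a, exponent)
      eg[j] <- mean(g)
      ea[j] <- if (mean(g) > 0) mean(a * g) / mean(g) else mean(a)
    }
    tibble(age_group = groups$age_group[i],
           multiplier = 1 / mean(eg), time_offset = mean(ea))
  })
  list_rbind(res)
}

#' @rdname brass_coefs
#' @param path CSV with columns `age_group`, `multiplier`, `time_offset`.
#' @export
read_coefs <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  miss <- setdiff(c("age_group", "multiplier", "time_offset"), names(df))
  if (length(miss)) abort(sprintf("coefficient CSV lacks columns: %s", paste(miss, collapse = ", ")))
  df
}

sbh_prepare <- function(table, coefs, exclude_groups) {
  req <- c("age_group", "ceb", "cd")
  miss <- setdiff(req, names(table))
  if (length(miss)) abort(sprintf("SBH table lacks columns: %s", paste(miss, collapse = ", ")))
  if (any(table$cd > table$ceb)) abort("children dead exceed children ever born in some rows")
  if (!"province" %in% names(table)) table$province <- NA_character_
  table <- table[!table$age_group %in% exclude_groups, , drop = FALSE]
  dropped <- table$ceb == 0
  if (any(dropped)) {
    warn(sprintf("dropping %d SBH rows with zero children ever born", sum(dropped)))
    table <- table[!dropped, , drop = FALSE]
  }
  counts <- table %>% group_by(.data$province) %>% summarise(n = n(), .groups = "drop")
  if (any(counts$n < 3)) abort("need at least 3 maternal age groups with ceb > 0")
  inner_join(table, coefs, by = "age_group")
}

#' Indirect U5MR estimates from summary birth histories
#'
#' `mac_estimate()` produces one observation per maternal age cohort:
#' `1000 * cd/ceb` scaled by the cohort multiplier, referenced to
#' `survey_year - time_offset`. `map_estimate()` regroups the same ratios by
#' the time period before the survey (5-year buckets of the reference-time
#' offsets), pooling cohorts that fall in the same period with
#' children-ever-born weights.
#'
#' @param table an SBH tibble: `age_group`, `ceb`, `cd` (plus optional
#'   `province` and QC columns).
#' @param survey_year calendar year of the survey.
#' @param coefs a coefficient set, see [brass_coefs()].
#' @param exclude_groups maternal age groups dropped before estimation. The
#'   youngest group is excluded by default, following the standard practice
#'   that its sparse, highly-multiplied ratios are unreliable.
#' @return An observation tibble (one row per cohort / period bucket).
#' @export
mac_estimate <- function(table, survey_year, coefs = brass_coefs(),
                         exclude_groups = "15-19") {
  dat <- sbh_prepare(table, coefs, exclude_groups)
  dat %>%
    mutate(value = pmin(1000 * .data$cd / .data$ceb * .data$multiplier, 999.9),
           year = survey_year - .data$time_offset,
           design_variance = 1 / (.data$cd + 0.5)) %>%
    mutate(source = "SBH_MAC", measure = "U5MR",
           completeness_adjustable = FALSE, completeness = NA_real_) %>%
    select("source", "province", "year", "measure", "value",
           "design_variance", "completeness_adjustable", "completeness")
}

#' @rdname mac_estimate
#' @export
map_estimate <- function(table, survey_year, coefs = brass_coefs(),
                         exclude_groups = "15-19") {
  dat <- sbh_prepare(table, coefs, exclude_groups)
  dat %>%
    mutate(q = 1000 * .data$cd / .data$ceb * .data$multiplier,
           bucket = floor(.data$time_offset / 5)) %>%
    group_by(.data$province, .data$bucket) %>%
    summarise(value = pmin(weighted.mean(.data$q, .data$ceb), 999.9),
              year = survey_year - weighted.mean(.data$time_offset, .data$ceb),
              design_variance = 1 / (sum(.data$cd) + 0.5),
              .groups = "drop") %>%
    mutate(source = "SBH_MAP", measure = "U5MR",
           completeness_adjustable = FALSE, completeness = NA_real_) %>%
    select("source", "province", "year", "measure", "value",
           "design_variance", "completeness_adjustable", "completeness")
}

#' @rdname mac_estimate
#' @param path CSV path for an SBH table / birth-record file.
#' @export
read_sbh <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  miss <- setdiff(c("age_group", "ceb", "cd"), names(df))
  if (length(miss)) abort(sprintf("SBH CSV lacks columns: %s", paste(miss, collapse = ", ")))
  df
}

#' @rdname mac_estimate
#' @export
read_birth_records <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  miss <- setdiff(c("birth_time", "alive", "age_at_death_months", "weight"), names(df))
  if (length(miss)) abort(sprintf("birth-record CSV lacks columns: %s", paste(miss, collapse = ", ")))
  df$alive <- as.logical(df$alive)
  df
}
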