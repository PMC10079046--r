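#' Annual rate of reduction
#'
#' The exponential decline rate between two rates:
#' `ARR = log(rate_t1 / rate_t2) / (t2 - t1)`, in natural-log units per year,
#' positive when the rate declines. Multiplied by 100 it is the percentage
#' AARR conventionally reported.
#'
#' @param rate_t1,rate_t2 positive rates at times `t1 < t2` (vectorized).
#' @param t1,t2 times (years).
#' @return The annual rate of reduction (per year, natural-log scale).
#' @export
#' @examples
#' 100 * arr(21.7, 15.2, 2010, 2017) # ~5.1% per year
arr <- function(rate_t1, rate_t2, t1, t2) {
  if (any(rate_t1 <= 0) || any(rate_t2 <= 0)) abort("rates must be positive")
  if (any(t2 <= t1)) abort("`t2` must exceed `t1`")
  log(rate_t1 / rate_t2) / (t2 - t1)
}

#' Scenario definition for NMR projection
#'
#' Five scenarios project provincial NMR from the base year to the horizon
#' with per-province annual rates of reduction (ARR):
#'
#' * `S1_constant` — rates frozen at the base year (ARR 0).
#' * `S2_own_trend` — each province keeps its own observed AARR.
#' * `S3_regional_best` — each province adopts the best (largest) AARR in its
#'   region.
#' * `S4_sdg_target` — provinces above the SDG threshold decline exactly to
#'   the threshold by the horizon; provinces already at or below it keep
#'   their own trend.
#' * `S5_richest_trend` — all provinces adopt the mean AARR of a designated
#'   set of highest-income provinces.
#'
#' @param id scenario identifier.
#' @param base_year,horizon projection span (base-year rates are reproduced
#'   exactly at `base_year`).
#' @param sdg_threshold SDG 3.2 neonatal threshold, deaths per 1,000.
#' @param regions tibble `province`, `region` (required for S3).
#' @param rich_provinces character vector (required for S5).
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(id = c("S1_constant", "S2_own_trend", "S3_regional_best",
                                 "S4_sdg_target", "S5_richest_trend"),
                          base_year = 2017, horizon = 2030, sdg_threshold = 12,
                          regions = NULL, rich_provinces = NULL) {
  id <- match.arg(id)
  if (horizon <= base_year) abort("`horizon` must exceed `base_year`")
  if (sdg_threshold <= 0) abort("`sdg_threshold` must be positive")
  structure(list(id = id, base_year = base_year, horizon = horizon,
                 sdg_threshold = sdg_threshold, regions = regions,
                 rich_provinces = rich_provinces),
            class = "scenario_spec")
}

#' Project NMR under a scenario
#'
#' Each province follows `NMR(t) = NMR(base) * exp(-ARR * (t - base))` with
#' the scenario's ARR. Death counts require live births over the projection
#' years; without them the death paths and the live-birth-weighted national
#' rate are `NA`.
#'
#' @param base_rates tibble `province`, `rate` — rates at the base year
#'   (deaths per 1,000 live births).
#' @param spec a [scenario_spec()].
#' @param aarr tibble `province`, `aarr` (per-year, natural-log units), the
#'   observed AARRs; required by S2, S3, S4 and S5.
#' @param live_births optional tibble `province`, `births` (held constant over
#'   the projection) or `province`, `year`, `births`.
#' @return An object of class `projection_result`: `path` (tibble `province`,
#'   `year`, `rate`, `deaths`), `cumulative_deaths` and `deaths_2030`-style
#'   totals over the years after the base year, `national_rate_horizon`,
#'   `sdg_flags` (tibble `province`, `achieved`), and the spec.
#' @export
project_scenario <- function(base_rates, spec, aarr = NULL, live_births = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!all(c("province", "rate") %in% names(base_rates))) {
    abort("`base_rates` needs `province` and `rate` columns")
  }
  if (any(base_rates$rate <= 0)) abort("base rates must be positive")
  provs <- base_rates$province
  if (spec$id == "S3_regional_best" && is.null(spec$regions)) {
    abort("S3_regional_best needs `regions` in the scenario spec")
  }
  if (spec$id == "S5_richest_trend" && is.null(spec$rich_provinces)) {
    abort("S5_richest_trend needs `rich_provinces` in the scenario spec")
  }
  need_aarr <- spec$id != "S1_constant"
  if (need_aarr) {
    if (is.null(aarr)) abort(sprintf("scenario %s needs an `aarr` table", spec$id))
    own <- aarr$aarr[match(provs, aarr$province)]
    if (anyNA(own)) {
      abort(sprintf("`aarr` table lacks provinces: %s",
                    paste(provs[is.na(own)], collapse = ", ")))
    }
  }
  arr_p <- switch(spec$id,
    S1_constant = rep(0, length(provs)),
    S2_own_trend = own,
    S3_regional_best = {
      if (is.null(spec$regions)) abort("S3_regional_best needs `regions` in the scenario spec")
      reg <- spec$regions$region[match(provs, spec$regions$province)]
      if (anyNA(reg)) {
        abort(sprintf("region mapping lacks provinces: %s",
                      paste(provs[is.na(reg)], collapse = ", ")))
      }
      best <- tapply(own, reg, max)
      as.vector(best[reg])
    },
    S4_sdg_target = {
      span <- spec$horizon - spec$base_year
      ifelse(base_rates$rate > spec$sdg_threshold,
             log(base_rates$rate / spec$sdg_threshold) / span, own)
    },
    S5_richest_trend = {
      if (is.null(spec$rich_provinces)) abort("S5_richest_trend needs `rich_provinces` in the scenario spec")
      sel <- match(spec$rich_provinces, provs)
      if (anyNA(sel)) {
        abort(sprintf("rich province set lacks base rates for: %s",
                      paste(spec$rich_provinces[is.na(sel)], collapse = ", ")))
      }
      rep(mean(own[sel]), length(provs))
    }
  )

  years <- spec$base_year:spec$horizon
  path <- crossing(province = provs, year = years) %>%
    mutate(rate = base_rates$rate[match(.data$province, provs)] *
             exp(-arr_p[match(.data$province, provs)] * (.data$year - spec$base_year)))

  births_of <- function(province, year) {
    if (is.null(live_births)) return(rep(NA_real_, length(province)))
    if ("year" %in% names(live_births)) {
      idx <- match(paste(province, year), paste(live_births$province, live_births$year))
      live_births$births[idx]
    } else {
      live_births$births[match(province, live_births$province)]
    }
  }
  path$deaths <- path$rate / 1000 * births_of(path$province, path$year)

  proj <- path %>% filter(.data$year > spec$base_year)
  horizon_rates <- path %>% filter(.data$year == spec$horizon)
  national <- if (!anyNA(horizon_rates$deaths)) {
    weighted.mean(horizon_rates$rate, births_of(horizon_rates$province, spec$horizon))
  } else NA_real_
  structure(list(
    spec = spec,
    path = path,
    cumulative_deaths = if (!anyNA(proj$deaths)) round_half_up(sum(proj$deaths)) else NA_real_,
    deaths_horizon = if (!anyNA(horizon_rates$deaths)) round_half_up(sum(horizon_rates$deaths)) else NA_real_,
    national_rate_horizon = national,
    sdg_flags = tibble(province = horizon_rates$province,
                       achieved = horizon_rates$rate <= spec$sdg_threshold + 1e-9)
  ), class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("<projection_result> %s %d-%d: %d/%d provinces reach NMR <= %.3g\n",
              x$spec$id, x$spec$base_year, x$spec$horizon,
              sum(x$sdg_flags$achieved), nrow(x$sdg_flags), x$spec$sdg_threshold))
  invisible(x)
}

#' @export
tidy.projection_result <- function(x, ...) x$path

#' @export
glance.projection_result <- function(x, ...) {
  tibble(scenario = x$spec$id, base_year = x$spec$base_year,
         horizon = x$spec$horizon,
         cumulative_deaths = x$cumulative_deaths,
         deaths_horizon = x$deaths_horizon,
         national_rate_horizon = x$national_rate_horizon,
         n_achieved = sum(x$sdg_flags$achieved))
}

#' Lives saved between two projection scenarios
#'
#' Difference in cumulative deaths over the projection years,
#' `cumulative(a) - cumulative(b)`: positive when scenario `b` saves lives
#' relative to scenario `a`.
#'
#' @param result_a,result_b [project_scenario()] results on the same horizon
#'   and live-birth inputs.
#' @return A number (count of deaths averted).
#' @export
lives_saved <- function(result_a, result_b) {
  stopifnot(inherits(result_a, "projection_result"), inherits(result_b, "projection_result"))
  if (result_a$spec$base_year != result_b$spec$base_year ||
      result_a$spec$horizon != result_b$spec$horizon) {
    abort("projection horizons differ")
  }
  if (is.na(result_a$cumulative_deaths) || is.na(result_b$cumulative_deaths)) {
    abort("both projections need live births to compare death counts")
  }
  result_a$cumulative_deaths - result_b$cumulative_deaths
}
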