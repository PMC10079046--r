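#' Configuration for the synthetic mortality panel generator
#'
#' The generator is the testing ground for the whole estimation pipeline: it
#' draws a latent province-year U5MR surface from the same ingredients the
#' stage models assume (log-linear covariate predictor, intrinsic-CAR spatial
#' effect, second-order random-walk temporal effect, independent interaction
#' noise), derives NMR through the quadratic log-log relation truncated at
#' U5MR, and then produces the observable data sources: death-registration
#' counts thinned by incompleteness, summary birth histories and complete
#' birth histories.
#'
#' Defaults define the standard desk-scale fixture: 8 provinces on a grid,
#' 2 regions, years 2005--2017. Registration completeness defaults to i.i.d.
#' uniform draws on (0.6, 0.95) per province-year; the lower end of observed
#' national completeness is documented only as a bound in the source
#' registries, so this range is a documented stand-in.
#'
#' @param n_provinces number of provinces (>= 4).
#' @param years inclusive integer year range (span >= 3).
#' @param graph_model adjacency topology, see [make_adjacency()].
#' @param mean_coefs intercept + 3 covariate slopes for log(U5MR per 1,000).
#' @param spatial_sd,temporal_sd,interaction_sd,obs_sd non-negative SDs of the
#'   CAR spatial effect, RW2 innovations, province-year interaction, and
#'   multiplicative (log-scale, mean-preserving) observation noise on DRS.
#' @param completeness_range sub-interval of (0, 1] for DRS completeness.
#' @param completeness_time `"iid"` draws completeness independently per
#'   province-year; `"constant"` draws one value per province held over time.
#' @param births_per_province_year baseline live births per province-year.
#' @param nmr_quad_coefs `c(beta0, beta1, beta2)` of
#'   `log(NMR) = b0 + b1 log(U5MR) + b2 log(U5MR)^2 + effect`.
#' @param nmr_effect_sd SD of the province-year NMR effects.
#' @param n_regions number of (contiguous-by-label) regions.
#' @param parities mean children ever born per mother for the seven 5-year
#'   maternal age groups 15-19 ... 45-49 (fixed fertility schedule).
#' @param seed integer seed; identical config + seed gives bit-identical output.
#'
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_provinces = 8,
                         years = 2005:2017,
                         graph_model = "grid",
                         mean_coefs = c(3.0, -0.15, -0.10, -0.10),
                         spatial_sd = 0.15,
                         temporal_sd = 0.01,
                         interaction_sd = 0.05,
                         obs_sd = 0.05,
                         completeness_range = c(0.6, 0.95),
                         completeness_time = c("iid", "constant"),
                         births_per_province_year = 20000,
                         nmr_quad_coefs = c(-0.7, 1.0, 0.03),
                         nmr_effect_sd = 0.05,
                         n_regions = 2,
                         parities = c(0.25, 1.0, 1.9, 2.7, 3.3, 3.7, 3.9),
                         seed = 20170101) {
  completeness_time <- match.arg(completeness_time)
  years <- sort(unique(as.integer(years)))
  if (n_provinces < 4) abort("`n_provinces` must be at least 4")
  if (length(years) < 3) abort("`years` must span at least 3 years")
  if (!all(diff(years) == 1)) abort("`years` must be contiguous")
  if (length(mean_coefs) != 4) abort("`mean_coefs` = intercept + 3 slopes")
  for (nm in c("spatial_sd", "temporal_sd", "interaction_sd", "obs_sd", "nmr_effect_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 0) abort(sprintf("`%s` must be a non-negative number", nm))
  }
  if (length(completeness_range) != 2 || completeness_range[1] <= 0 ||
      completeness_range[2] > 1 || completeness_range[1] > completeness_range[2]) {
    abort("`completeness_range` must be a sub-interval of (0, 1]")
  }
  stop_if_not_scalar_number(births_per_province_year, "births_per_province_year", positive = TRUE)
  if (length(nmr_quad_coefs) != 3) abort("`nmr_quad_coefs` must be length 3")
  if (length(parities) != 7 || any(parities <= 0)) abort("`parities` must be 7 positive values")
  structure(
    list(n_provinces = as.integer(n_provinces), years = years,
         graph_model = graph_model, mean_coefs = mean_coefs,
         spatial_sd = spatial_sd, temporal_sd = temporal_sd,
         interaction_sd = interaction_sd, obs_sd = obs_sd,
         completeness_range = completeness_range,
         completeness_time = completeness_time,
         births_per_province_year = as.integer(births_per_province_year),
         nmr_quad_coefs = nmr_quad_coefs, nmr_effect_sd = nmr_effect_sd,
         n_regions = as.integer(n_regions), parities = parities,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Cumulative fraction of under-5 death risk experienced by exact age `a` years.
# Front-loaded (concave) to reflect the concentration of under-5 deaths at the
# youngest ages; shared by the SBH generator and calibrated_sbh_coefs().
u5_cum_frac <- function(a, exponent = 0.4) {
  pmin(pmax(a, 0) / 5, 1)^exponent
}

#' Generate the latent ground truth panel
#'
#' Draws the true U5MR and NMR surfaces, covariates, completeness, live births,
#' adjacency and region membership defined by a [synth_config()]. Everything is
#' deterministic given the config seed.
#'
#' @param config a [synth_config()].
#' @return An object of class `synth_truth`: a list with `true_u5mr` and
#'   `true_nmr` (province x year matrices, deaths per 1,000), `covariates`
#'   (tibble), `completeness` and `live_births` matrices, `adjacency` (igraph),
#'   `regions` (tibble `province`, `region`), `rich_provinces` (provinces of
#'   the region with the highest mean wealth covariate), and `components`
#'   (the spatial / temporal / interaction / NMR-effect draws, kept for
#'   parameter-recovery tests).
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  P <- config$n_provinces
  years <- config$years
  T_ <- length(years)

  with_seed(config$seed, {
    graph <- make_adjacency(P, config$graph_model, seed = config$seed)
    provinces <- igraph::V(graph)$name

    # smooth, roughly standardized province-year covariates
    t_sc <- (years - mean(years)) / (diff(range(years)) / 2)
    base <- matrix(rnorm(P * 3), P, 3)
    slope <- matrix(rnorm(P * 3, mean = 0.3, sd = 0.1), P, 3)
    cov_arr <- array(NA_real_, c(P, T_, 3))
    for (k in 1:3) cov_arr[, , k] <- base[, k] + outer(slope[, k], t_sc)

    spatial <- if (config$spatial_sd > 0) {
      as.vector(sample_constrained_gmrf(icar_structure_scaled(graph), config$spatial_sd))
    } else rep(0, P)

    temporal <- if (config$temporal_sd > 0) {
      g <- numeric(T_)
      for (t in 3:T_) g[t] <- 2 * g[t - 1] - g[t - 2] + rnorm(1, 0, config$temporal_sd)
      g - mean(g)
    } else rep(0, T_)

    interaction <- matrix(rnorm(P * T_, 0, config$interaction_sd), P, T_)

    b <- config$mean_coefs
    log_u5 <- b[1] + b[2] * cov_arr[, , 1] + b[3] * cov_arr[, , 2] +
      b[4] * cov_arr[, , 3] + spatial + rep(temporal, each = P) + interaction
    true_u5mr <- exp(log_u5)

    nb <- config$nmr_quad_coefs
    nmr_effects <- matrix(rnorm(P * T_, 0, config$nmr_effect_sd), P, T_)
    log_nmr <- nb[1] + nb[2] * log_u5 + nb[3] * log_u5^2 + nmr_effects
    true_nmr <- pmin(exp(log_nmr), true_u5mr)

    if (any(true_u5mr >= 1000) || any(true_nmr <= 0)) {
      abort("config implies rates outside (0, 1000) per 1,000; adjust mean_coefs/SDs")
    }

    completeness <- switch(config$completeness_time,
      iid = matrix(runif(P * T_, config$completeness_range[1], config$completeness_range[2]), P, T_),
      constant = matrix(rep(runif(P, config$completeness_range[1], config$completeness_range[2]), T_), P, T_)
    )

    births_p <- pmax(1L, as.integer(round(config$births_per_province_year *
                                            exp(rnorm(P, 0, 0.15)))))
    live_births <- matrix(rep(births_p, T_), P, T_)

    region_id <- ceiling(seq_len(P) / ceiling(P / config$n_regions))
    regions <- tibble(province = provinces,
                      region = sprintf("region_%d", region_id))
    mean_wealth <- tapply(rowMeans(cov_arr[, , 1]), region_id, mean)
    rich_region <- sprintf("region_%s", names(which.max(mean_wealth)))
    rich_provinces <- regions$province[regions$region == rich_region]

    dimnames(true_u5mr) <- dimnames(true_nmr) <- dimnames(completeness) <-
      dimnames(live_births) <- dimnames(interaction) <- dimnames(nmr_effects) <-
      list(provinces, years)

    covariates <- tibble(
      province = rep(provinces, times = T_),
      year = rep(years, each = P),
      wealth = as.vector(cov_arr[, , 1]),
      schooling = as.vector(cov_arr[, , 2]),
      urbanization = as.vector(cov_arr[, , 3])
    )

    structure(
      list(config = config, provinces = provinces, years = years,
           true_u5mr = true_u5mr, true_nmr = true_nmr,
           covariates = covariates, completeness = completeness,
           live_births = live_births, adjacency = graph, regions = regions,
           rich_provinces = rich_provinces,
           components = list(spatial = spatial, temporal = temporal,
                             interaction = interaction, nmr_effects = nmr_effects)),
      class = "synth_truth"
    )
  })
}

#' Simulated death-registration observations
#'
#' Registered under-5 and neonatal death counts are Binomial draws with success
#' probability `completeness x rate / 1000` (times mean-preserving log-normal
#' observation noise when `obs_sd > 0`), so the expected registered rate is
#' `completeness` times the true rate. The returned observations carry the true
#' completeness for synthetic diagnostics; the estimation models never see it.
#'
#' @param truth a [generate_truth()] result.
#' @param seed RNG seed (defaults to the truth seed + 1).
#' @param measures which measures to register.
#' @return A tibble of observations in the standard schema (see
#'   [validate_observations()]), with `deaths` and `live_births` columns kept.
#' @export
generate_drs <- function(truth, seed = truth$config$seed + 1,
                         measures = c("U5MR", "NMR")) {
  stopifnot(inherits(truth, "synth_truth"))
  obs_sd <- truth$config$obs_sd
  with_seed(seed, {
    out <- map(measures, function(ms) {
      rate <- if (ms == "U5MR") truth$true_u5mr else truth$true_nmr
      noise <- if (obs_sd > 0) {
        matrix(exp(rnorm(length(rate), 0, obs_sd) - obs_sd^2 / 2), nrow(rate), ncol(rate))
      } else 1
      p <- pmin(rate / 1000 * truth$completeness * noise, 1)
      counts <- matrix(rbinom(length(p), as.vector(truth$live_births), as.vector(p)),
                       nrow(p), ncol(p))
      tibble(
        source = "DRS",
        province = rep(truth$provinces, times = length(truth$years)),
        year = rep(truth$years, each = length(truth$provinces)),
        measure = ms,
        deaths = as.vector(counts),
        live_births = as.vector(truth$live_births),
        value = 1000 * pmax(as.vector(counts), 0.5) / as.vector(truth$live_births),
        design_variance = 1 / pmax(as.vector(counts), 0.5),
        completeness_adjustable = TRUE,
        completeness = as.vector(truth$completeness)
      )
    })
    list_rbind(out)
  })
}

#' Simulated summary birth histories
#'
#' For each province and 5-year maternal age group, mothers' children ever born
#' (CEB) follow the fixed parity schedule of the config; each birth is exposed
#' to the true under-5 risk of its birth cohort, scaled by the fraction of
#' under-5 risk already experienced at the child's current age, to give
#' children dead (CD).
#'
#' @param truth a [generate_truth()] result.
#' @param survey_year calendar year of the survey (within or after the panel).
#' @param n_mothers_per_agegroup mothers sampled per province-age-group.
#' @param seed RNG seed.
#' @param missing_fraction reported missing-value fraction carried on each row
#'   (a QC attribute; the counts themselves are complete).
#' @return A tibble: `province`, `age_group`, `ceb`, `cd`, `n_mothers`,
#'   `missing_fraction`, with `cd <= ceb` everywhere.
#' @export
generate_sbh <- function(truth, survey_year, n_mothers_per_agegroup = 120,
                         seed = truth$config$seed + 2, missing_fraction = 0) {
  stopifnot(inherits(truth, "synth_truth"))
  if (survey_year < min(truth$years)) abort("`survey_year` must be within or after the panel years")
  groups <- sbh_age_groups()
  with_seed(seed, {
    rows <- list()
    for (p in seq_along(truth$provinces)) {
      for (i in seq_len(nrow(groups))) {
        n <- n_mothers_per_agegroup
        u <- runif(n, groups$lower[i], groups$lower[i] + 5)
        ceb_i <- rpois(n, truth$config$parities[i])
        ceb <- sum(ceb_i)
        cd <- 0L
        if (ceb > 0) {
          mother_age <- rep(u, ceb_i)
          a <- runif(ceb, 0, pmax(mother_age - 15, 0.25))
          birth_year <- pmin(pmax(round(survey_year - a), min(truth$years)), max(truth$years))
          q5 <- truth$true_u5mr[p, match(birth_year, truth$years)] / 1000
          prob <- q5 * u5_cum_frac(a)
          cd <- sum(runif(ceb) < prob)
        }
        rows[[length(rows) + 1]] <- tibble(
          province = truth$provinces[p], age_group = groups$age_group[i],
          ceb = as.integer(ceb), cd = as.integer(cd),
          n_mothers = as.integer(n), missing_fraction = missing_fraction
        )
      }
    }
    list_rbind(rows)
  })
}

#' Simulated complete birth histories
#'
#' Individual child records with month-resolution birth dates. Deaths are drawn
#' from a piecewise-constant hazard: the first completed month carries the full
#' neonatal risk `NMR/1000` of the child's birth cohort, and months 1--59 share
#' the remaining under-5 risk so the total probability of death before 60
#' months equals `U5MR/1000`. Children are censored alive at the survey date.
#'
#' @param truth a [generate_truth()] result.
#' @param survey_year survey mid-year; births fall in the preceding 12 years.
#' @param n_mothers mothers sampled per province.
#' @param seed RNG seed.
#' @param mean_births mean births per mother over the window.
#' @return A tibble of records: `province`, `birth_time` (fractional calendar
#'   year at month resolution), `alive`, `age_at_death_months` (integer in
#'   `[0, 60)`, `NA` when alive), `weight`.
#' @export
generate_cbh <- function(truth, survey_year, n_mothers = 300,
                         seed = truth$config$seed + 3, mean_births = 2.2) {
  stopifnot(inherits(truth, "synth_truth"))
  survey_time <- survey_year + 0.5
  with_seed(seed, {
    rows <- list()
    for (p in seq_along(truth$provinces)) {
      n_births <- sum(rpois(n_mothers, mean_births))
      if (n_births == 0) next
      month_back <- floor(runif(n_births, 0, 144)) # up to 12 years before survey
      birth_time <- survey_time - (month_back + 0.5) / 12
      birth_year <- pmin(pmax(floor(birth_time), min(truth$years)), max(truth$years))
      yi <- match(birth_year, truth$years)
      q5 <- truth$true_u5mr[p, yi] / 1000
      qn <- pmin(truth$true_nmr[p, yi] / 1000, q5)
      u <- runif(n_births)
      h1 <- log((1 - qn) / (1 - q5)) / 59
      death_month <- rep(NA_integer_, n_births)
      neonatal <- u < qn
      death_month[neonatal] <- 0L
      later <- !neonatal & u < q5
      if (any(later)) {
        m_star <- log((1 - qn[later]) / (1 - u[later])) / h1[later]
        death_month[later] <- pmax(1L, pmin(59L, as.integer(ceiling(m_star))))
      }
      age_at_survey <- floor((survey_time - birth_time) * 12)
      dead <- !is.na(death_month) & death_month < pmin(60L, age_at_survey)
      rows[[length(rows) + 1]] <- tibble(
        province = truth$provinces[p],
        birth_time = birth_time,
        alive = !dead,
        age_at_death_months = ifelse(dead, death_month, NA_integer_),
        weight = exp(rnorm(n_births, 0, 0.2))
      )
    }
    list_rbind(rows)
  })
}

#' Standard observation set from a synthetic truth
#'
#' Composes the observable data sources the estimation stages consume:
#' registration (DRS) panels for U5MR and NMR, indirect cohort and period
#' estimates from two summary-birth-history surveys (mid-panel and end of
#' panel), and direct complete-birth-history estimates for the six years
#' before the end-of-panel survey. Survey sizes default to census/DHS-like
#' scales so that zero-death cells — which cannot enter the log-scale stage
#' models — are rare.
#'
#' @param truth a [generate_truth()] result.
#' @param seed RNG seed for all sources.
#' @param sbh_years summary-birth-history survey years.
#' @param cbh_year complete-birth-history survey year.
#' @param sbh_mothers mothers per province and age group.
#' @param cbh_mothers mothers per province.
#' @param coefs indirect-estimation coefficient set.
#' @return A list: `u5mr` and `nmr` observation tibbles, plus the raw `drs`,
#'   `sbh` tables and `cbh` records.
#' @export
synthetic_observations <- function(truth, seed = truth$config$seed + 1,
                                   sbh_years = NULL, cbh_year = NULL,
                                   sbh_mothers = 400, cbh_mothers = 1200,
                                   coefs = calibrated_sbh_coefs()) {
  stopifnot(inherits(truth, "synth_truth"))
  yrs <- truth$years
  sbh_years <- sbh_years %||% c(yrs[ceiling(length(yrs) / 2)], max(yrs))
  cbh_year <- cbh_year %||% max(yrs)
  drs <- generate_drs(truth, seed = seed)
  u5 <- drs %>% filter(.data$measure == "U5MR") %>% select(-"deaths", -"live_births")
  sbh <- map(setNames(sbh_years, paste0("sbh_", sbh_years)), function(sy) {
    generate_sbh(truth, sy, n_mothers_per_agegroup = sbh_mothers,
                 seed = seed + 100 + sy)
  })
  indirect <- imap(sbh, function(tbl, nm) {
    sy <- as.integer(sub("sbh_", "", nm))
    bind_rows(mac_estimate(tbl, sy, coefs = coefs),
              map_estimate(tbl, sy, coefs = coefs))
  }) %>% list_rbind() %>% filter(.data$year >= min(yrs))
  cbh <- generate_cbh(truth, cbh_year, n_mothers = cbh_mothers, seed = seed + 200)
  direct <- map(seq(cbh_year - 6, cbh_year - 1), function(yy) {
    split(cbh, cbh$province) %>% map(~ cbh_u5mr(.x, yy)) %>% list_rbind()
  }) %>% list_rbind()
  list(
    u5mr = bind_rows(u5, indirect, direct) %>% filter(.data$value > 0),
    nmr = drs %>% filter(.data$measure == "NMR") %>% select(-"deaths", -"live_births"),
    drs = drs, sbh = sbh, cbh = cbh
  )
}

sbh_age_groups <- function() {
  lower <- seq(15, 45, by = 5)
  tibble(age_group = sprintf("%d-%d", lower, lower + 4), lower = lower)
}

#' Write all synthetic tables of a truth object to a directory
#'
#' Emits `truth_u5mr.csv` / `truth_nmr.csv` (long province-year rates),
#' `covariates.csv`, `completeness.csv`, `live_births.csv`, `adjacency.csv`
#' (edge list), `regions.csv` and `config.yaml`.
#'
#' @param truth a [generate_truth()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- function(m, col) {
    tibble(province = rep(rownames(m), times = ncol(m)),
           year = rep(as.integer(colnames(m)), each = nrow(m)),
           !!col := as.vector(m))
  }
  write.csv(long(truth$true_u5mr, "true_u5mr"), file.path(dir, "truth_u5mr.csv"), row.names = FALSE)
  write.csv(long(truth$true_nmr, "true_nmr"), file.path(dir, "truth_nmr.csv"), row.names = FALSE)
  write.csv(long(truth$completeness, "completeness"), file.path(dir, "completeness.csv"), row.names = FALSE)
  write.csv(long(truth$live_births, "live_births"), file.path(dir, "live_births.csv"), row.names = FALSE)
  write.csv(truth$covariates, file.path(dir, "covariates.csv"), row.names = FALSE)
  write.csv(truth$regions, file.path(dir, "regions.csv"), row.names = FALSE)
  write_adjacency(truth$adjacency, file.path(dir, "adjacency.csv"))
  cfg <- truth$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
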