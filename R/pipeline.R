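#' End-to-end pipeline configuration
#'
#' Bundles every stage specification, the global seed and the output
#' directory. All stage seeds are derived deterministically from the global
#' seed, so a config reproduces the whole run bit-for-bit.
#'
#' @param out_dir output directory for stage CSVs and the manifest.
#' @param seed global seed.
#' @param synth a [synth_config()] (its seed is overridden by `seed`).
#' @param gpr,st,holdout,nmr stage specifications; `NULL` uses defaults wired
#'   to the global seed.
#' @param scenarios scenario ids to project (see [scenario_spec()]).
#' @param sbh_survey_years,cbh_survey_year survey placements.
#' @param sbh_mothers,cbh_mothers survey sizes per province (per age group
#'   for SBH).
#' @param sbh_coefs coefficient set for the indirect estimators.
#' @param verbose log one line per stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("sdgmort_run_"), seed = 1,
                       synth = NULL, gpr = NULL, st = NULL, holdout = NULL,
                       nmr = NULL,
                       scenarios = c("S1_constant", "S2_own_trend",
                                     "S3_regional_best", "S4_sdg_target",
                                     "S5_richest_trend"),
                       sbh_survey_years = NULL, cbh_survey_year = NULL,
                       sbh_mothers = 400, cbh_mothers = 1200,
                       sbh_coefs = calibrated_sbh_coefs(), verbose = TRUE) {
  seed <- as.integer(seed)
  synth <- synth %||% synth_config(seed = seed)
  synth$seed <- seed
  gpr <- gpr %||% gpr_spec(mcmc = list(chains = 2, warmup = 150, draws = 100, seed = seed))
  st <- st %||% st_spec(inference = list(method = "gibbs", chains = 2,
                                         warmup = 150, draws = 100, seed = seed))
  holdout <- holdout %||% holdout_plan(seed = seed + 7)
  nmr <- nmr %||% nmr_spec(gpr = gpr, st = st,
                           holdout = holdout_plan(seed = seed + 8),
                           n_out_draws = 2 * gpr$mcmc$draws, seed = seed + 9)
  structure(list(out_dir = out_dir, seed = seed, synth = synth, gpr = gpr,
                 st = st, holdout = holdout, nmr = nmr, scenarios = scenarios,
                 sbh_survey_years = sbh_survey_years,
                 cbh_survey_year = cbh_survey_year,
                 sbh_mothers = sbh_mothers, cbh_mothers = cbh_mothers,
                 sbh_coefs = sbh_coefs, verbose = verbose),
            class = "run_config")
}

#' Run the full estimation pipeline on synthetic data
#'
#' Executes the six stages in order — simulate, birth-history estimation
#' (with the data-quality gate), stage-model fitting, ensemble averaging,
#' NMR estimation, projection and summary — writing each stage's outputs as
#' CSV under the config's output directory together with a manifest of
#' seeds, timings and file checksums. Any stage failure aborts with the
#' stage named.
#'
#' @param config a [run_config()].
#' @return A list with all stage results and the `manifest` tibble.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  results <- list()
  log_line <- function(...) if (config$verbose) message(sprintf(...))

  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fn(), error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
    files <- out$files %||% character()
    sums <- if (length(files)) unname(tools::md5sum(files)) else character()
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = name, seconds = round(proc.time()[["elapsed"]] - t0, 2),
      seed = config$seed, outputs = paste(basename(files), collapse = ";"),
      checksum = if (length(sums)) paste(sums, collapse = ";") else ""
    )
    log_line("stage %-14s done in %6.2fs (seed %d)", name,
             proc.time()[["elapsed"]] - t0, config$seed)
    out
  }

  od <- config$out_dir
  fp <- function(...) file.path(od, ...)

  # 1 -- simulate ------------------------------------------------------------
  sim <- run_stage("simulate", function() {
    truth <- generate_truth(config$synth)
    drs <- generate_drs(truth, seed = config$seed + 1)
    yrs <- truth$years
    sbh_years <- config$sbh_survey_years %||% c(yrs[ceiling(length(yrs) / 2)], max(yrs))
    cbh_year <- config$cbh_survey_year %||% max(yrs)
    sbh <- imap(setNames(sbh_years, paste0("sbh_", sbh_years)), function(sy, nm) {
      generate_sbh(truth, sy, n_mothers_per_agegroup = config$sbh_mothers,
                   seed = config$seed + 100 + sy)
    })
    cbh <- generate_cbh(truth, cbh_year, n_mothers = config$cbh_mothers,
                        seed = config$seed + 200)
    write_synthetic(truth, fp("synthetic"))
    write_observations(drs, fp("drs_observations.csv"))
    files <- c(fp("drs_observations.csv"),
               fp("synthetic", c("truth_u5mr.csv", "truth_nmr.csv", "covariates.csv",
                                 "completeness.csv", "live_births.csv", "adjacency.csv",
                                 "regions.csv", "config.yaml")))
    list(truth = truth, drs = drs, sbh = sbh, cbh = cbh,
         sbh_years = sbh_years, cbh_year = cbh_year, files = files)
  })

  # 2 -- birth-history estimation -------------------------------------------
  bh <- run_stage("birth_history", function() {
    # synthetic surveys are complete with a plausible sex ratio; the gate is
    # exercised here exactly as it would be on real inputs
    qc <- qc_gate(list(missing_fraction = 0.005, sex_ratio = 1.02))
    if (!qc$accept) abort(qc$reason)
    indirect <- imap(sim$sbh, function(tbl, nm) {
      sy <- as.integer(sub("sbh_", "", nm))
      bind_rows(mac_estimate(tbl, sy, coefs = config$sbh_coefs),
                map_estimate(tbl, sy, coefs = config$sbh_coefs))
    }) %>% list_rbind()
    # keep indirect estimates inside the panel years
    indirect <- indirect %>% filter(.data$year >= min(sim$truth$years))
    direct <- map(seq(sim$cbh_year - 6, sim$cbh_year - 1), function(yy) {
      split(sim$cbh, sim$cbh$province) %>%
        map(~ cbh_u5mr(.x, yy)) %>% list_rbind()
    }) %>% list_rbind()
    u5_obs <- bind_rows(sim$drs %>% filter(.data$measure == "U5MR") %>%
                          select(-"deaths", -"live_births"),
                        indirect, direct) %>%
      filter(.data$value > 0)
    write_observations(u5_obs, fp("u5mr_observations.csv"))
    list(u5_obs = u5_obs, files = fp("u5mr_observations.csv"))
  })

  # 3 -- stage models ---------------------------------------------------------
  stage <- run_stage("stage_models", function() {
    truth <- sim$truth
    mean_fit <- fit_glmm_mean(bh$u5_obs, truth$covariates)
    gpr_fit <- fit_gpr(bh$u5_obs, mean_fit, truth$adjacency, config$gpr,
                       covariates = truth$covariates, years = truth$years)
    c_hat <- mean(gpr_fit$hyper$completeness_DRS %||% 1)
    st_obs <- bh$u5_obs %>%
      mutate(value = ifelse(isTRUE_vec(.data$completeness_adjustable),
                            .data$value / c_hat, .data$value))
    st_fit <- fit_st(st_obs, truth$adjacency, config$st, years = truth$years)
    write_surface(gpr_fit, fp("u5mr_gpr.csv"))
    write_surface(st_fit, fp("u5mr_st.csv"))
    list(mean_fit = mean_fit, gpr = gpr_fit, st = st_fit, c_hat = c_hat,
         files = c(fp("u5mr_gpr.csv"), fp("u5mr_st.csv")))
  })

  # 4 -- ensemble --------------------------------------------------------------
  ens <- run_stage("ensemble", function() {
    truth <- sim$truth
    ho <- make_holdout(bh$u5_obs, config$holdout)
    mean_tr <- fit_glmm_mean(ho$train, truth$covariates)
    gpr_tr <- fit_gpr(ho$train, mean_tr, truth$adjacency, config$gpr,
                      covariates = truth$covariates, years = truth$years)
    st_tr_obs <- ho$train %>%
      mutate(value = ifelse(isTRUE_vec(.data$completeness_adjustable),
                            .data$value / stage$c_hat, .data$value))
    st_tr <- fit_st(st_tr_obs, truth$adjacency, config$st, years = truth$years)
    scores <- score_models(list(GPR = gpr_tr, ST = st_tr), ho$test,
                           drs_completeness = stage$c_hat)
    scores <- rank_weights(scores)
    combined <- combine_surfaces(list(GPR = stage$gpr, ST = stage$st), scores,
                                 seed = config$seed + 20)
    write.csv(scores, fp("model_scores.csv"), row.names = FALSE)
    write_surface(combined, fp("u5mr_combined.csv"))
    list(scores = scores, combined = combined,
         files = c(fp("model_scores.csv"), fp("u5mr_combined.csv")))
  })

  # 5 -- NMR -------------------------------------------------------------------
  nmr <- run_stage("nmr", function() {
    nmr_obs <- sim$drs %>% filter(.data$measure == "NMR") %>%
      select(-"deaths", -"live_births")
    spec <- config$nmr
    spec$drs_completeness <- stage$c_hat
    fit <- fit_nmr(nmr_obs, ens$combined, sim$truth$adjacency, spec)
    write_surface(fit, fp("nmr_combined.csv"))
    write.csv(tidy(fit$relation), fp("nmr_relation.csv"), row.names = FALSE)
    list(fit = fit, files = c(fp("nmr_combined.csv"), fp("nmr_relation.csv")))
  })

  # 6 -- projection & summary --------------------------------------------------
  proj <- run_stage("project_summarize", function() {
    truth <- sim$truth
    yrs <- truth$years
    nmr_med <- surface_median(nmr$fit)
    u5_med <- surface_median(ens$combined)
    t1 <- yrs[max(1, length(yrs) - 7)]
    t2 <- max(yrs)
    aarr_tbl <- tibble(province = truth$provinces,
                       aarr = arr(nmr_med[, as.character(t1)],
                                  nmr_med[, as.character(t2)], t1, t2))
    base <- tibble(province = truth$provinces, rate = nmr_med[, as.character(t2)])
    births <- tibble(province = truth$provinces, births = truth$live_births[, 1])
    projections <- map(setNames(config$scenarios, config$scenarios), function(sc) {
      project_scenario(base, scenario_spec(sc, base_year = t2, horizon = t2 + 13,
                                           regions = truth$regions,
                                           rich_provinces = truth$rich_provinces),
                       aarr = aarr_tbl, live_births = births)
    })
    summary_tbl <- tibble(
      area = truth$provinces,
      !!sprintf("u5mr_%d", t1) := u5_med[, as.character(t1)],
      !!sprintf("u5mr_%d", t2) := u5_med[, as.character(t2)],
      !!sprintf("nmr_%d", t1) := nmr_med[, as.character(t1)],
      !!sprintf("nmr_%d", t2) := nmr_med[, as.character(t2)]
    ) %>% panel_summary(t1 = t1, t2 = t2)
    proj_glance <- map(projections, glance) %>% list_rbind()
    write.csv(summary_tbl, fp("panel_summary.csv"), row.names = FALSE)
    write.csv(proj_glance, fp("projections.csv"), row.names = FALSE)
    list(projections = projections, summary = summary_tbl, aarr = aarr_tbl,
         files = c(fp("panel_summary.csv"), fp("projections.csv")))
  })

  manifest_tbl <- list_rbind(manifest)
  write.csv(manifest_tbl, fp("manifest.csv"), row.names = FALSE)
  list(truth = sim$truth, observations = bh$u5_obs, mean_fit = stage$mean_fit,
       gpr = stage$gpr, st = stage$st, scores = ens$scores,
       combined = ens$combined, nmr = nmr$fit, projections = proj$projections,
       summary = proj$summary, manifest = manifest_tbl, out_dir = od)
}
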