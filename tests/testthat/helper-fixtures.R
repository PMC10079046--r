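# shared fixtures: built in code, deterministic given seeds

# default desk-scale fixture (8 provinces x 2005-2017)
default_truth <- function(seed = 20170101, ...) {
  generate_truth(synth_config(seed = seed, ...))
}

# noise-free configuration: the latent surface is exactly the covariate
# predictor, so generator inversions are exact
noisefree_config <- function(seed = 1, mean_coefs = c(3.0, -0.15, -0.10, -0.10)) {
  synth_config(mean_coefs = mean_coefs, spatial_sd = 0, temporal_sd = 0,
               interaction_sd = 0, obs_sd = 0, nmr_effect_sd = 0, seed = seed)
}

# exact observations straight from the truth surface (no sampling noise)
exact_observations <- function(truth, design_variance = 1e-6, measure = "U5MR") {
  rate <- if (measure == "U5MR") truth$true_u5mr else truth$true_nmr
  tibble::tibble(
    source = "CBH", # non-adjustable source: values are taken at face value
    province = rep(truth$provinces, times = length(truth$years)),
    year = rep(truth$years, each = length(truth$provinces)),
    measure = measure,
    value = as.vector(rate),
    design_variance = design_variance,
    completeness_adjustable = FALSE,
    completeness = NA_real_
  )
}

# fast mcmc settings for smoke-level fits
smoke_mcmc <- function(seed = 1) list(chains = 2, warmup = 100, draws = 75, seed = seed)

smoke_gpr <- function(seed = 1, ...) gpr_spec(mcmc = smoke_mcmc(seed), ...)

smoke_st <- function(seed = 1, method = "gibbs") {
  st_spec(inference = list(method = method, chains = 2, warmup = 100,
                           draws = 75, seed = seed))
}

# constant-valued surface helper for ensemble arithmetic tests
constant_surface <- function(values, provinces, years, n_draws = 50,
                             measure = "U5MR", model_tag = "const") {
  stopifnot(length(values) == length(provinces) * length(years))
  draws <- array(rep(values, n_draws),
                 c(length(provinces), length(years), n_draws))
  rate_surface(draws, provinces, years, measure = measure, model_tag = model_tag)
}

# one ensemble replicate on the default fixture: fit both stage models on the
# training split, score on the holdout, combine, and return coverage of the
# truth by the combined 95% intervals (plus the pieces for further checks)
ensemble_replicate <- function(rep_seed, return_fits = FALSE) {
  truth <- default_truth(seed = rep_seed)
  ob <- synthetic_observations(truth, seed = rep_seed + 1)
  ho <- make_holdout(ob$u5mr, holdout_plan(seed = rep_seed + 7))
  mean_fit <- fit_glmm_mean(ho$train, truth$covariates)
  gpr_fit <- fit_gpr(ho$train, mean_fit, truth$adjacency, smoke_gpr(rep_seed),
                     covariates = truth$covariates, years = truth$years)
  c_hat <- mean(gpr_fit$hyper$completeness_DRS)
  st_obs <- dplyr::mutate(ho$train,
                          value = ifelse(completeness_adjustable, value / c_hat, value))
  st_fit <- fit_st(st_obs, truth$adjacency, smoke_st(rep_seed), years = truth$years)
  scores <- rank_weights(score_models(list(GPR = gpr_fit, ST = st_fit), ho$test,
                                      drs_completeness = c_hat))
  combined <- combine_surfaces(list(GPR = gpr_fit, ST = st_fit), scores,
                               seed = rep_seed + 20)
  s <- summary(combined)
  tv <- as.vector(t(truth$true_u5mr))
  out <- list(coverage = mean(tv >= s$lower95 & tv <= s$upper95),
              scores = scores, c_hat = c_hat, truth = truth)
  if (return_fits) {
    out$gpr <- gpr_fit; out$st <- st_fit; out$combined <- combined; out$obs <- ob
  }
  out
}
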