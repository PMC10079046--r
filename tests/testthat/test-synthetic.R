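test_that("generation is bit-identical given seed and config", {
  t1 <- default_truth()
  t2 <- default_truth()
  expect_identical(t1$true_u5mr, t2$true_u5mr)
  expect_identical(t1$true_nmr, t2$true_nmr)
  expect_identical(t1$completeness, t2$completeness)
  expect_identical(generate_drs(t1, seed = 5), generate_drs(t2, seed = 5))
  expect_identical(generate_sbh(t1, 2017, seed = 5), generate_sbh(t2, 2017, seed = 5))
  expect_identical(generate_cbh(t1, 2017, seed = 5), generate_cbh(t2, 2017, seed = 5))
})

test_that("noise-free truth equals the covariate predictor exactly", {
  cfg <- noisefree_config(seed = 11)
  truth <- generate_truth(cfg)
  b <- cfg$mean_coefs
  pred <- truth$covariates %>%
    dplyr::mutate(mu = exp(b[1] + b[2] * wealth + b[3] * schooling + b[4] * urbanization))
  got <- truth$true_u5mr[cbind(match(pred$province, truth$provinces),
                               match(pred$year, truth$years))]
  expect_equal(got, pred$mu, tolerance = 1e-12)
})

test_that("NMR is truncated at U5MR even when the relation predicts above it", {
  cfg <- synth_config(nmr_quad_coefs = c(1.0, 1.1, 0.0), nmr_effect_sd = 0,
                      seed = 4)
  truth <- generate_truth(cfg)
  expect_true(all(truth$true_nmr <= truth$true_u5mr))
  expect_true(any(truth$true_nmr == truth$true_u5mr)) # truncation actually bites
  expect_true(all(truth$true_nmr > 0))
})

test_that("RW2 temporal prior matches its closed-form lag-1 autocorrelation", {
  sd_t <- 0.05
  T_ <- 13
  n_rep <- 500
  cfg0 <- synth_config(spatial_sd = 0, interaction_sd = 0, temporal_sd = sd_t)
  num <- den <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg0$seed <- 5000L + r
    g <- generate_truth(cfg0)$components$temporal
    num[r] <- sum(g[-T_] * g[-1])
    den[r] <- sum(g^2)
  }
  emp <- sum(num) / sum(den)
  # oracle: covariance of the centred double-cumulative-sum process, built
  # directly from the recursion g_t = 2 g_{t-1} - g_{t-2} + z_t, g_1 = g_2 = 0
  B <- matrix(0, T_, T_) # g = B %*% z with z_t the innovation at time t
  for (t in 3:T_) for (r in 3:t) B[t, r] <- t - r + 1
  S <- sd_t^2 * B %*% t(B)
  H <- diag(T_) - 1 / T_
  C <- H %*% S %*% H
  theo <- sum(C[cbind(1:(T_ - 1), 2:T_)]) / sum(diag(C))
  # Monte-Carlo error from batching the replicates
  batch <- rep(1:10, each = n_rep / 10)
  ratios <- tapply(num, batch, sum) / tapply(den, batch, sum)
  mc_se <- sd(ratios) / sqrt(10)
  expect_lt(abs(emp - theo), 4 * mc_se + 1e-6)
})

test_that("registered deaths follow the thinned binomial", {
  cfg <- synth_config(mean_coefs = c(log(20), 0, 0, 0), spatial_sd = 0,
                      temporal_sd = 0, interaction_sd = 0, obs_sd = 0,
                      completeness_range = c(0.5, 0.5),
                      births_per_province_year = 50000, seed = 21)
  truth <- generate_truth(cfg)
  tot_births <- sum(truth$live_births)
  set.seed(1)
  counts <- replicate(60, sum(dplyr::filter(generate_drs(truth, seed = sample.int(1e6, 1)),
                                            measure == "U5MR")$deaths))
  expected <- tot_births * 20 / 1000 * 0.5
  mc_se <- sqrt(tot_births * 0.01 * 0.99) / sqrt(60)
  expect_lt(abs(mean(counts) - expected), 4 * mc_se)
  # support: counts never exceed births
  drs <- generate_drs(truth, seed = 9)
  expect_true(all(drs$deaths <= drs$live_births))
})

test_that("zero-mortality truth yields no deaths in any source", {
  cfg <- synth_config(mean_coefs = c(-15, 0, 0, 0), spatial_sd = 0,
                      temporal_sd = 0, interaction_sd = 0, obs_sd = 0, seed = 3)
  truth <- generate_truth(cfg)
  drs <- generate_drs(truth, seed = 4)
  expect_true(all(drs$deaths == 0))
  sbh <- generate_sbh(truth, 2017, seed = 5)
  expect_true(all(sbh$cd == 0))
  cbh <- generate_cbh(truth, 2017, seed = 6)
  expect_true(all(cbh$alive))
})

test_that("SBH tables and CBH records satisfy their support invariants", {
  truth <- default_truth()
  sbh <- generate_sbh(truth, 2017, seed = 8)
  expect_true(all(sbh$cd <= sbh$ceb))
  expect_true(all(sbh$ceb >= 0))
  cbh <- generate_cbh(truth, 2017, seed = 8)
  dead <- !cbh$alive
  expect_true(all(cbh$age_at_death_months[dead] >= 0))
  expect_true(all(cbh$age_at_death_months[dead] < 60))
  expect_true(all(is.na(cbh$age_at_death_months[!dead])))
  expect_true(all(cbh$weight > 0))
})

test_that("doubling the true surface roughly doubles SBH death ratios", {
  base <- synth_config(mean_coefs = c(log(15), 0, 0, 0), spatial_sd = 0,
                       temporal_sd = 0, interaction_sd = 0, seed = 31)
  dbl <- synth_config(mean_coefs = c(log(30), 0, 0, 0), spatial_sd = 0,
                      temporal_sd = 0, interaction_sd = 0, seed = 31)
  ratio_of <- function(cfg) {
    truth <- generate_truth(cfg)
    r <- numeric(30)
    for (k in seq_len(30)) {
      tbl <- generate_sbh(truth, 2017, n_mothers_per_agegroup = 200,
                          seed = 900 + k)
      r[k] <- sum(tbl$cd) / sum(tbl$ceb)
    }
    mean(r)
  }
  expect_equal(ratio_of(dbl) / ratio_of(base), 2, tolerance = 0.06)
})

test_that("expected registration rate is completeness times the true rate", {
  truth <- default_truth(seed = 77)
  set.seed(2)
  vals <- replicate(200, {
    drs <- dplyr::filter(generate_drs(truth, seed = sample.int(1e6, 1)),
                         measure == "U5MR")
    mean(1000 * drs$deaths / drs$live_births /
           (as.vector(truth$true_u5mr) * as.vector(truth$completeness)))
  })
  expect_equal(mean(vals), 1, tolerance = 0.01)
})

test_that("synthetic tables round-trip through the CSV writers", {
  truth <- default_truth()
  dir <- withr::local_tempdir()
  write_synthetic(truth, dir)
  adj <- read_adjacency(file.path(dir, "adjacency.csv"))
  expect_setequal(igraph::V(adj)$name, truth$provinces)
  expect_equal(igraph::gsize(adj), igraph::gsize(truth$adjacency))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg$seed, truth$config$seed)
  obs <- synthetic_observations(truth)
  f <- file.path(dir, "obs.csv")
  write_observations(obs$u5mr, f)
  back <- read_observations(f)
  expect_equal(nrow(back), nrow(obs$u5mr))
  expect_equal(back$value, obs$u5mr$value, tolerance = 1e-12)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_provinces = 3), "at least 4")
  expect_error(synth_config(years = 2010:2011), "at least 3")
  expect_error(synth_config(completeness_range = c(0, 0.9)), "sub-interval")
  expect_error(synth_config(completeness_range = c(0.5, 1.2)), "sub-interval")
  expect_error(synth_config(spatial_sd = -1), "non-negative")
})
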