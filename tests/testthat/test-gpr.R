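test_that("kernels are valid correlations", {
  expect_equal(matern_corr(0, 1.5, 5), 1)
  d <- 0:10
  k <- matern_corr(d, 1.5, 5)
  expect_true(all(diff(k) < 0))
  expect_true(all(k > 0 & k <= 1))

  g <- make_adjacency(8, "grid")
  Ks <- graph_diffusion_kernel(g, 0.7)
  expect_equal(diag(Ks), rep(1, 8))
  expect_true(min(eigen(Ks, symmetric = TRUE, only.values = TRUE)$values) > -1e-10)
  # closer nodes correlate more strongly than graph-distant ones
  dmat <- igraph::distances(g)
  far <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
  near <- which(dmat == 1, arr.ind = TRUE)[1, ]
  expect_gt(Ks[near[1], near[2]], Ks[far[1], far[2]])
})

test_that("mean model reduces to the mean log rate with no usable covariates", {
  obs <- tibble::tibble(source = "CBH", province = "P01", year = 2010:2014,
                        measure = "U5MR", value = c(10, 12, 14, 13, 11),
                        design_variance = 0.01,
                        completeness_adjustable = FALSE, completeness = NA_real_)
  covs <- tibble::tibble(province = "P01", year = 2010:2014, wealth = 0)
  fit <- suppressMessages(fit_glmm_mean(obs, covs))
  expect_equal(unname(fit$coefficients[["(Intercept)"]]), mean(log(obs$value)),
               tolerance = 1e-10)
})

test_that("mean model inverts the generator exactly on noise-free data", {
  cfg <- noisefree_config(seed = 7)
  truth <- generate_truth(cfg)
  obs <- exact_observations(truth)
  fit <- fit_glmm_mean(obs, truth$covariates)
  est <- fit$coefficients[c("(Intercept)", "wealth", "schooling", "urbanization")]
  expect_equal(unname(est), cfg$mean_coefs, tolerance = 1e-6)

  # shifting all log observations by c moves only the intercept
  shifted <- dplyr::mutate(obs, value = value * exp(0.3))
  fit2 <- fit_glmm_mean(shifted, truth$covariates)
  expect_equal(unname(fit2$coefficients[["(Intercept)"]] - fit$coefficients[["(Intercept)"]]),
               0.3, tolerance = 1e-6)
  expect_equal(unname(fit2$coefficients[-1]), unname(fit$coefficients[-1]),
               tolerance = 1e-6)
})

test_that("collinear covariates raise an error naming the columns", {
  truth <- default_truth()
  obs <- exact_observations(truth)
  covs <- dplyr::mutate(truth$covariates, wealth2 = wealth * 2)
  expect_error(fit_glmm_mean(obs, covs), "wealth2|wealth")
})

test_that("GP posterior interpolates dense precise observations", {
  truth <- generate_truth(synth_config(n_provinces = 4, years = 2010:2015,
                                       seed = 12))
  obs <- exact_observations(truth, design_variance = 1e-8)
  spec <- gpr_spec(method = "map", nonsampling_sd_prior = c(default = 1e-4),
                   mcmc = list(chains = 1, warmup = 0, draws = 200, seed = 2))
  fit <- fit_gpr(obs, NULL, truth$adjacency, spec, years = truth$years)
  med <- surface_median(fit)
  expect_lt(max(abs(med - truth$true_u5mr) / truth$true_u5mr), 0.01)
})

test_that("a point-mass completeness of one half doubles the registered rate", {
  truth <- generate_truth(synth_config(n_provinces = 4, years = 2010:2015,
                                       seed = 13))
  obs <- exact_observations(truth, design_variance = 1e-8) %>%
    dplyr::mutate(source = "DRS", value = value * 0.5,
                  completeness_adjustable = TRUE)
  spec <- gpr_spec(method = "map", completeness_fixed = c(DRS = 0.5),
                   nonsampling_sd_prior = c(default = 1e-4),
                   mcmc = list(chains = 1, warmup = 0, draws = 200, seed = 2))
  fit <- fit_gpr(obs, NULL, truth$adjacency, spec, years = truth$years)
  med <- surface_median(fit)
  expect_equal(med / (0.5 * truth$true_u5mr), matrix(2, 4, 6,
               dimnames = dimnames(med)), tolerance = 0.02)
})

test_that("posterior draws are reproducible and label-exchangeable", {
  truth <- generate_truth(synth_config(n_provinces = 4, years = 2010:2014,
                                       seed = 14))
  obs <- exact_observations(truth, design_variance = 0.01)
  spec <- gpr_spec(mcmc = list(chains = 2, warmup = 30, draws = 30, seed = 5))
  f1 <- fit_gpr(obs, NULL, truth$adjacency, spec, years = truth$years)
  f2 <- fit_gpr(obs, NULL, truth$adjacency, spec, years = truth$years)
  expect_identical(f1$draws, f2$draws)

  # permute province labels (exchangeable spatial kernel): posterior permutes
  spec_ex <- gpr_spec(spatial_kernel = "exchangeable", method = "map",
                      mcmc = list(chains = 1, warmup = 0, draws = 3000, seed = 5))
  perm <- c(3, 1, 4, 2)
  relabel <- setNames(truth$provinces[perm], truth$provinces)
  obs_p <- dplyr::mutate(obs, province = unname(relabel[province]))
  fa <- fit_gpr(obs, NULL, truth$adjacency, spec_ex, years = truth$years)
  fb <- fit_gpr(obs_p, NULL, truth$adjacency, spec_ex, years = truth$years)
  ma <- surface_median(fa)
  mb <- surface_median(fb)
  expect_equal(mb[relabel[truth$provinces], ], ma[truth$provinces, ],
               tolerance = 0.02, ignore_attr = TRUE)
})

test_that("with a single perfect source the posterior tracks the observations as noise vanishes", {
  truth <- generate_truth(synth_config(n_provinces = 4, years = 2010:2015, seed = 18))
  err <- vapply(c(0.05, 1e-6), function(v) {
    obs <- exact_observations(truth, design_variance = v)
    fit <- fit_gpr(obs, NULL, truth$adjacency,
                   gpr_spec(method = "map", nonsampling_sd_prior = c(default = 1e-4),
                            mcmc = list(chains = 1, warmup = 0, draws = 100, seed = 3)),
                   years = truth$years)
    mean(abs(surface_median(fit) - truth$true_u5mr) / truth$true_u5mr)
  }, 0)
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.01)
})

test_that("surfaces round-trip through CSV", {
  truth <- generate_truth(synth_config(n_provinces = 4, years = 2010:2013, seed = 2))
  obs <- exact_observations(truth, design_variance = 0.01)
  fit <- fit_gpr(obs, NULL, truth$adjacency,
                 gpr_spec(method = "map", mcmc = list(chains = 1, warmup = 0, draws = 20, seed = 1)),
                 years = truth$years)
  f <- file.path(withr::local_tempdir(), "surf.csv")
  write_surface(fit, f)
  back <- read_surface(f)
  expect_equal(back$draws, fit$draws, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(back$measure, "U5MR")
})
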