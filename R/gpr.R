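#' Matérn and spatial kernels
#'
#' The GPR stage model uses a separable space-time covariance: a Matérn
#' correlation in time (smoothness `nu` controls differentiability, the length
#' scale controls how fast the time trend decorrelates) times a spatial
#' correlation over the province graph, either a graph-diffusion (heat) kernel
#' on the adjacency Laplacian or an exchangeable correlation.
#'
#' @param d non-negative distances (years).
#' @param nu Matérn smoothness (> 0).
#' @param ell length scale (> 0, same units as `d`).
#' @return `matern_corr()`: correlations in `[0, 1]`.
#' @export
matern_corr <- function(d, nu, ell) {
  stopifnot(nu > 0, ell > 0)
  x <- sqrt(2 * nu) * abs(d) / ell
  out <- ifelse(x == 0, 1,
                2^(1 - nu) / gamma(nu) * x^nu * besselK(pmax(x, 1e-12), nu))
  pmin(out, 1)
}

#' @rdname matern_corr
#' @param graph province adjacency graph.
#' @param theta diffusion time of the heat kernel (larger = smoother over the
#'   graph).
#' @return `graph_diffusion_kernel()`: a province correlation matrix.
#' @export
graph_diffusion_kernel <- function(graph, theta = 0.7) {
  L <- icar_structure(graph)
  e <- eigen(L, symmetric = TRUE)
  K <- e$vectors %*% (exp(-theta * e$values) * t(e$vectors))
  d <- sqrt(diag(K))
  K / outer(d, d)
}


#' @rdname matern_corr
#' @param n_provinces number of provinces.
#' @param rho common correlation.
#' @export
exchangeable_kernel <- function(n_provinces, rho = 0.3) {
  stopifnot(rho >= 0, rho < 1)
  m <- matrix(rho, n_provinces, n_provinces)
  diag(m) <- 1
  m
}

#' Specification of the Gaussian-process stage model
#'
#' @param matern_smoothness Matérn smoothness of the time kernel.
#' @param length_scale_time time length scale in years.
#' @param spatial_kernel `"adjacency-diffusion"` or `"exchangeable"`.
#' @param spatial_theta diffusion time of the graph kernel.
#' @param exchangeable_rho correlation of the exchangeable kernel.
#' @param amplitude_sd prior scale of the GP amplitude (log-rate scale).
#' @param completeness_prior `c(shape1, shape2)` of the Beta prior on the
#'   shared completeness of each adjustable source.
#' @param completeness_fixed optional named numeric: point-mass completeness
#'   per adjustable source (overrides the Beta prior).
#' @param nonsampling_sd_prior named half-normal scales of the per-source
#'   non-sampling SD (log scale); unnamed sources fall back to `default`.
#' @param mcmc list `chains`, `warmup`, `draws` (per chain), `seed`.
#' @param method `"gibbs"` (blocked Gibbs/Metropolis MCMC; the latent field
#'   update is exact multivariate-normal conditioning) or `"map"`
#'   (hyperparameters fixed at prior means, exact Gaussian conditional draws —
#'   deterministic given the seed; intended for smoke tests).
#' @return A list of class `gpr_spec`.
#' @export
gpr_spec <- function(matern_smoothness = 1.5, length_scale_time = 5,
                     spatial_kernel = c("adjacency-diffusion", "exchangeable"),
                     spatial_theta = 0.7, exchangeable_rho = 0.3,
                     amplitude_sd = 0.3,
                     completeness_prior = c(6, 2),
                     completeness_fixed = NULL,
                     nonsampling_sd_prior = c(DRS = 0.12, SBH_MAC = 0.15,
                                              SBH_MAP = 0.15, CBH = 0.12,
                                              default = 0.15),
                     mcmc = list(chains = 2, warmup = 200, draws = 150, seed = 1),
                     method = c("gibbs", "map")) {
  spatial_kernel <- match.arg(spatial_kernel)
  method <- match.arg(method)
  for (nm in c("matern_smoothness", "length_scale_time", "spatial_theta", "amplitude_sd")) {
    stop_if_not_scalar_number(get(nm), nm, positive = TRUE)
  }
  mcmc <- utils::modifyList(list(chains = 2, warmup = 200, draws = 150, seed = 1), mcmc)
  if (mcmc$draws < 10) abort("need at least 10 posterior draws")
  if (length(completeness_prior) != 2 || any(completeness_prior <= 0)) {
    abort("`completeness_prior` must be two positive Beta parameters")
  }
  structure(list(matern_smoothness = matern_smoothness,
                 length_scale_time = length_scale_time,
                 spatial_kernel = spatial_kernel, spatial_theta = spatial_theta,
                 exchangeable_rho = exchangeable_rho, amplitude_sd = amplitude_sd,
                 completeness_prior = completeness_prior,
                 completeness_fixed = completeness_fixed,
                 nonsampling_sd_prior = nonsampling_sd_prior,
                 mcmc = mcmc, method = method),
            class = "gpr_spec")
}

#' Covariate mixed-model mean for the GPR stage
#'
#' Fits the log-linear mean `log(rate) ~ covariates + (1 | province)` by
#' inverse-design-variance weighted (RE)ML, giving the mean function the GP is
#' centred on. Constant covariate columns are dropped with a message; genuinely
#' collinear columns are an error naming the columns. With fewer than three
#' provinces the random intercept is dropped and a weighted linear model is
#' used.
#'
#' @param observations observation tibble (see [validate_observations()]).
#' @param covariates tibble `province`, `year` plus numeric covariate columns.
#' @return An object of class `glmm_mean_fit` with `tidy()`, `glance()` and
#'   internal prediction support; `$residuals` holds per-observation
#'   `log(value) - fitted`.
#' @export
fit_glmm_mean <- function(observations, covariates) {
  validate_observations(observations)
  obs <- observations %>% filter(.data$value > 0)
  if (nrow(obs) < nrow(observations)) {
    warn(sprintf("dropping %d non-positive observations before taking logs",
                 nrow(observations) - nrow(obs)))
  }
  cov_cols <- setdiff(names(covariates), c("province", "year"))
  if (!length(cov_cols)) abort("`covariates` has no covariate columns")
  panel_years <- sort(unique(covariates$year))
  obs$year_panel <- panel_years[pmax(1, pmin(length(panel_years),
                                             findInterval(obs$year + 0.5, panel_years)))]
  dat <- inner_join(obs, covariates, by = c(province = "province", year_panel = "year"))
  if (nrow(dat) < nrow(obs)) abort("covariates do not cover all observation province-years")
  if (anyNA(dat[cov_cols])) abort("covariates contain missing values")

  keep <- cov_cols[vapply(dat[cov_cols], function(x) var(x) > 0, logical(1))]
  dropped <- setdiff(cov_cols, keep)
  if (length(dropped)) {
    inform(sprintf("dropping constant covariate column(s): %s", paste(dropped, collapse = ", ")))
  }
  dat$.logv <- log(dat$value)
  dat$.w <- 1 / pmax(dat$design_variance, 1e-6)

  if (length(keep)) {
    X <- model.matrix(stats::reformulate(keep), dat)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
      abort(sprintf("collinear covariate column(s): %s", paste(bad, collapse = ", ")))
    }
  }

  use_re <- length(unique(dat$province)) >= 3
  if (use_re) {
    fml <- stats::as.formula(paste(".logv ~", if (length(keep)) paste(keep, collapse = " + ") else "1",
                                   "+ (1 | province)"))
    model <- suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = dat, weights = dat$.w, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE))
    ))
    fixed <- lme4::fixef(model)
    re <- lme4::ranef(model)$province
    ranef_tbl <- tibble(province = rownames(re), intercept = re[[1]])
    fitted_vals <- as.vector(stats::fitted(model))
  } else {
    fml <- stats::as.formula(paste(".logv ~", if (length(keep)) paste(keep, collapse = " + ") else "1"))
    model <- lm(fml, data = dat, weights = dat$.w)
    fixed <- coef(model)
    ranef_tbl <- tibble(province = character(), intercept = numeric())
    fitted_vals <- as.vector(stats::fitted(model))
  }
  res <- dat %>%
    mutate(.fitted = fitted_vals, .resid = .data$.logv - fitted_vals) %>%
    select("source", "province", "year", "measure", "value", "design_variance",
           ".fitted", ".resid")
  structure(list(model = model, coefficients = fixed, covariate_names = keep,
                 ranef = ranef_tbl, residuals = res, used_re = use_re),
            class = "glmm_mean_fit")
}

#' @export
print.glmm_mean_fit <- function(x, ...) {
  cat("<glmm_mean_fit> log-rate mean:", paste(names(x$coefficients), collapse = " + "), "\n")
  invisible(x)
}

#' @export
tidy.glmm_mean_fit <- function(x, ...) {
  se <- tryCatch(sqrt(diag(as.matrix(vcov(x$model)))), error = function(e) rep(NA_real_, length(x$coefficients)))
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients),
         std.error = unname(se))
}

#' @export
glance.glmm_mean_fit <- function(x, ...) {
  tibble(n_obs = nrow(x$residuals),
         n_provinces = length(unique(x$residuals$province)),
         resid_sd = sd(x$residuals$.resid),
         random_intercept = x$used_re)
}

# Mean prediction on a province-year grid. `newdata` must carry the covariate
# columns the fit used. Unseen provinces get a zero random intercept.
predict_mean <- function(fit, newdata) {
  stopifnot(inherits(fit, "glmm_mean_fit"))
  X <- model.matrix(stats::reformulate(if (length(fit$covariate_names)) fit$covariate_names else "1"),
                    newdata)
  mu <- as.vector(X %*% fit$coefficients[colnames(X)])
  if (nrow(fit$ranef)) {
    idx <- match(newdata$province, fit$ranef$province)
    mu <- mu + ifelse(is.na(idx), 0, fit$ranef$intercept[idx])
  }
  mu
}

# ---------------------------------------------------------------------------
# Shared Gaussian-field Gibbs engine.
#
# y_i = mu_obs_i + f_{cell(i)} + log(c_{source_i}) [adjustable only] + e_i,
# e_i ~ N(0, v0_i + sigma_ns[source_i]^2),  f ~ GP(0, amp^2 * K).
#
# Conditionals: f is exact MVN (conjugate); amp^2 inverse-gamma (conjugate);
# completeness and non-sampling SDs are random-walk Metropolis. `method="map"`
# freezes the hyperparameters at prior means and draws f exactly.
# ---------------------------------------------------------------------------
gp_field_engine <- function(y, v0, cell, n_cell, Kinv, source,
                            ns_scales, adjust, comp_prior, comp_fixed,
                            amplitude_sd, mcmc, method = "gibbs") {
  n <- length(y)
  src_levels <- unique(source)
  adj_sources <- unique(source[adjust])
  ns_scale_of <- function(s) {
    sc <- ns_scales[s]
    ifelse(is.na(sc), ns_scales["default"] %||% 0.15, sc)
  }
  comp_mean <- comp_prior[1] / sum(comp_prior)

  run_chain <- function(chain_seed) with_seed(chain_seed, {
    amp2 <- amplitude_sd^2
    sigma_ns <- setNames(vapply(src_levels, function(s) unname(ns_scale_of(s)) * 0.6, 0), src_levels)
    comp <- setNames(rep(comp_mean, length(adj_sources)), adj_sources)
    if (!is.null(comp_fixed)) {
      for (s in intersect(names(comp_fixed), adj_sources)) comp[s] <- comp_fixed[[s]]
    }
    f <- rep(0, n_cell)

    n_iter <- mcmc$warmup + mcmc$draws
    keep_f <- matrix(NA_real_, n_cell, mcmc$draws)
    keep_h <- matrix(NA_real_, mcmc$draws, 1 + length(adj_sources) + length(src_levels))
    colnames(keep_h) <- c("amplitude",
                          paste0("completeness_", adj_sources, recycle0 = TRUE),
                          paste0("sigma_ns_", src_levels, recycle0 = TRUE))

    offset <- function(comp) {
      off <- rep(0, n)
      for (s in adj_sources) off[adjust & source == s] <- log(comp[s])
      off
    }

    for (it in seq_len(n_iter)) {
      vv <- v0 + sigma_ns[source]^2
      w <- 1 / vv
      r <- y - offset(comp)
      if (method == "map") {
        # fixed hyperparameters: one exact conditional, draw all samples at once
        wc <- as.vector(rowsum(w, cell, reorder = FALSE))
        wc_full <- rep(0, n_cell); wc_full[as.integer(rownames(rowsum(w, cell, reorder = FALSE)))] <- wc
        bc <- rep(0, n_cell)
        bsum <- rowsum(w * r, cell, reorder = FALSE)
        bc[as.integer(rownames(bsum))] <- as.vector(bsum)
        Ppost <- Kinv / amp2 + diag(wc_full)
        R <- chol(Ppost)
        f_mean <- backsolve(R, forwardsolve(t(R), bc))
        Z <- matrix(rnorm(n_cell * mcmc$draws), n_cell, mcmc$draws)
        keep_f <- f_mean + backsolve(R, Z)
        keep_h[, "amplitude"] <- sqrt(amp2)
        for (s in adj_sources) keep_h[, paste0("completeness_", s)] <- comp[s]
        for (s in src_levels) keep_h[, paste0("sigma_ns_", s)] <- sigma_ns[s]
        break
      }
      # --- f | rest (exact) ---
      wc_full <- rep(0, n_cell)
      bsum_w <- rowsum(w, cell, reorder = FALSE)
      wc_full[as.integer(rownames(bsum_w))] <- as.vector(bsum_w)
      bc <- rep(0, n_cell)
      bsum <- rowsum(w * r, cell, reorder = FALSE)
      bc[as.integer(rownames(bsum))] <- as.vector(bsum)
      Ppost <- Kinv / amp2 + diag(wc_full)
      R <- chol(Ppost)
      f_mean <- backsolve(R, forwardsolve(t(R), bc))
      f <- f_mean + backsolve(R, rnorm(n_cell))

      # --- amplitude^2 | f (conjugate inverse-gamma) ---
      quad <- sum(f * (Kinv %*% f))
      amp2 <- 1 / rgamma(1, shape = 2 + n_cell / 2, rate = amplitude_sd^2 + quad / 2)

      resid_f <- y - f[cell]
      # --- completeness per adjustable source (Metropolis on logit scale) ---
      for (s in adj_sources) {
        if (!is.null(comp_fixed) && s %in% names(comp_fixed)) next
        sel <- adjust & source == s
        cur <- comp[s]
        prop <- plogis(qlogis(cur) + rnorm(1, 0, 0.2))
        ll <- function(cc) {
          sum(dnorm(resid_f[sel], log(cc), sqrt(vv[sel]), log = TRUE)) +
            dbeta(cc, comp_prior[1], comp_prior[2], log = TRUE) +
            log(cc) + log(1 - cc) # logit-scale Jacobian
        }
        if (log(runif(1)) < ll(prop) - ll(cur)) comp[s] <- prop
      }
      r2 <- resid_f - offset(comp)
      # --- non-sampling SD per source (Metropolis on log scale, half-normal prior) ---
      for (s in src_levels) {
        sel <- source == s
        cur <- sigma_ns[s]
        prop <- cur * exp(rnorm(1, 0, 0.25))
        sc <- unname(ns_scale_of(s))
        ll <- function(sg) {
          sum(dnorm(r2[sel], 0, sqrt(v0[sel] + sg^2), log = TRUE)) -
            sg^2 / (2 * sc^2) + log(sg)
        }
        if (log(runif(1)) < ll(prop) - ll(cur)) sigma_ns[s] <- prop
      }

      if (it > mcmc$warmup) {
        k <- it - mcmc$warmup
        keep_f[, k] <- f
        keep_h[k, "amplitude"] <- sqrt(amp2)
        for (s in adj_sources) keep_h[k, paste0("completeness_", s)] <- comp[s]
        for (s in src_levels) keep_h[k, paste0("sigma_ns_", s)] <- sigma_ns[s]
      }
    }
    list(f = keep_f, hyper = keep_h)
  })

  chains <- if (method == "map") 1 else mcmc$chains
  out <- map(seq_len(chains), function(ch) run_chain(mcmc$seed + ch * 1000))
  field <- do.call(cbind, map(out, "f"))
  hyper <- do.call(rbind, map(out, "hyper"))

  rh <- NA_real_
  if (chains >= 2) {
    probe <- unique(round(seq(1, n_cell, length.out = min(6, n_cell))))
    rh <- max(vapply(probe, function(j) {
      rhat(do.call(cbind, map(out, function(o) o$f[j, ])))
    }, 0), na.rm = TRUE)
    if (is.finite(rh) && rh > 1.05) {
      warn(sprintf("potential non-convergence: max R-hat %.3f > 1.05 over probed cells", rh))
    }
  }
  list(field = field, hyper = as_tibble(hyper), rhat = rh)
}

#' Fit the Gaussian-process stage model
#'
#' Posterior draws of the latent log-rate surface under a GP prior centred on
#' the covariate mixed-model mean, with separable Matérn-time x graph-spatial
#' covariance. Registration (`completeness_adjustable`) observations enter
#' with an additive log-completeness offset carrying a Beta prior shared
#' within source; every observation's variance is its design variance plus a
#' source-specific non-sampling variance with a half-normal prior on the SD.
#'
#' @param observations observation tibble, one `measure`.
#' @param mean_fit a [fit_glmm_mean()] result, or `NULL` for a zero mean.
#' @param adjacency province adjacency graph (igraph); all observation
#'   provinces must be vertices and the graph must be connected.
#' @param spec a [gpr_spec()].
#' @param covariates covariate panel covering all cells (required when
#'   `mean_fit` is given).
#' @param years optional explicit year grid (defaults to the span of the
#'   observation years).
#' @return An object of classes `gpr_fit` and [rate_surface()]; extra fields
#'   `hyper` (posterior hyperparameter draws) and `diagnostics`.
#' @export
fit_gpr <- function(observations, mean_fit, adjacency, spec = gpr_spec(),
                    covariates = NULL, years = NULL) {
  stopifnot(inherits(spec, "gpr_spec"))
  validate_observations(observations)
  if (!igraph::is_connected(adjacency)) abort("adjacency graph must be connected")
  ms <- unique(observations$measure)
  if (length(ms) != 1) abort("fit one measure at a time")
  obs <- observations %>% filter(.data$value > 0)
  if (nrow(obs) < nrow(observations)) {
    warn(sprintf("dropping %d non-positive observations", nrow(observations) - nrow(obs)))
  }
  provinces <- igraph::V(adjacency)$name
  if (!all(obs$province %in% provinces)) {
    abort("observations reference provinces absent from the adjacency graph")
  }
  years <- years %||% seq(floor(min(obs$year)), ceiling(max(obs$year)))
  P <- length(provinces); T_ <- length(years)

  p_idx <- match(obs$province, provinces)
  t_idx <- pmax(1, pmin(T_, round(obs$year) - years[1] + 1))
  cell <- (t_idx - 1L) * P + p_idx

  # with no covariate mean model, centre the GP on the pooled weighted mean
  # log rate so the amplitude prior only has to carry deviations
  mu_cell <- rep(weighted.mean(log(obs$value), 1 / pmax(obs$design_variance, 1e-8)),
                 P * T_)
  if (!is.null(mean_fit)) {
    if (is.null(covariates)) abort("`covariates` needed to evaluate the mean function on the grid")
    grid <- tibble(province = rep(provinces, times = T_), year = rep(years, each = P))
    grid <- left_join(grid, covariates, by = c("province", "year"))
    if (anyNA(grid)) abort("covariates do not cover the full province-year grid")
    mu_cell <- predict_mean(mean_fit, grid)
  }

  Ks <- switch(spec$spatial_kernel,
    `adjacency-diffusion` = graph_diffusion_kernel(adjacency, spec$spatial_theta),
    exchangeable = exchangeable_kernel(P, spec$exchangeable_rho)
  )
  Kt <- matern_corr(abs(outer(years, years, "-")), spec$matern_smoothness,
                    spec$length_scale_time)
  dim(Kt) <- c(T_, T_)
  es <- eigen(Ks, symmetric = TRUE); et <- eigen(Kt, symmetric = TRUE)
  lam <- pmax(as.vector(kronecker(et$values, es$values)), 1e-8)
  U <- kronecker(et$vectors, es$vectors)
  Kinv <- U %*% (t(U) / lam)

  y <- log(obs$value) - mu_cell[cell]
  fit <- gp_field_engine(
    y = y, v0 = pmax(obs$design_variance, 1e-8), cell = cell, n_cell = P * T_,
    Kinv = Kinv, source = obs$source,
    ns_scales = spec$nonsampling_sd_prior,
    adjust = if (is.null(obs$completeness_adjustable)) rep(FALSE, nrow(obs)) else isTRUE_vec(obs$completeness_adjustable),
    comp_prior = spec$completeness_prior, comp_fixed = spec$completeness_fixed,
    amplitude_sd = spec$amplitude_sd, mcmc = spec$mcmc, method = spec$method
  )

  S <- ncol(fit$field)
  lograte <- array(mu_cell + fit$field, c(P, T_, S))
  draws <- pmin(pmax(exp(lograte), 1e-4), 999.9)
  out <- rate_surface(draws, provinces, years, measure = ms,
                      model_tag = "GPR", seed = spec$mcmc$seed)
  out$hyper <- fit$hyper
  out$diagnostics <- list(rhat = fit$rhat, method = spec$method)
  out$spec <- spec
  class(out) <- c("gpr_fit", class(out))
  out
}

isTRUE_vec <- function(x) {
  if (is.null(x)) return(logical(0))
  !is.na(x) & x
}

#' @export
glance.gpr_fit <- function(x, ...) {
  tibble(measure = x$measure, n_draws = dim(x$draws)[3],
         method = x$diagnostics$method, max_rhat = x$diagnostics$rhat,
         mean_amplitude = mean(x$hyper$amplitude))
}
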