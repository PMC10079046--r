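#' Quadratic log-log relation between NMR and U5MR
#'
#' Pooled across province-years, log(NMR) is modeled as a quadratic function
#' of log(U5MR); province-year effects absorb departures from the global
#' curve, letting provinces run persistently above or below the NMR expected
#' from their U5MR. `fit_nmr_relation()` estimates the quadratic by weighted
#' least squares of completeness-corrected registration NMR values on the
#' posterior-median log U5MR; its residuals are the raw province-year effect
#' observations the effect models smooth.
#'
#' @param nmr_observations NMR observation tibble (registration panel).
#' @param u5mr_surface a U5MR [rate_surface()] covering the observations.
#' @param drs_completeness completeness correction applied to adjustable
#'   (registration) values before fitting.
#' @return An object of class `nmr_relation`: quadratic `coefficients`
#'   (`beta0`, `beta1`, `beta2`), their `vcov`, `residual_sd`, and
#'   `effects` — a tibble of per-observation residual effects with design
#'   variances.
#' @export
fit_nmr_relation <- function(nmr_observations, u5mr_surface, drs_completeness = 1) {
  validate_observations(nmr_observations)
  if (!all(nmr_observations$measure == "NMR")) abort("expected NMR observations")
  obs <- nmr_observations
  adj <- if (is.null(obs$completeness_adjustable)) rep(FALSE, nrow(obs)) else isTRUE_vec(obs$completeness_adjustable)
  obs$value_adj <- obs$value / ifelse(adj, drs_completeness, 1)
  obs <- obs %>% filter(.data$value_adj > 0)
  u5_med <- surface_median(u5mr_surface)
  p <- match(obs$province, u5mr_surface$provinces)
  t <- pmax(1, pmin(length(u5mr_surface$years),
                    round(obs$year) - u5mr_surface$years[1] + 1))
  if (anyNA(p)) abort("U5MR surface does not cover all NMR observation provinces")
  obs$lu <- log(u5_med[cbind(p, t)])
  high <- obs$value_adj > u5_med[cbind(p, t)]
  if (any(high)) {
    warn(sprintf("%d NMR observations exceed the paired U5MR median; they are kept and the fitted surface is truncated", sum(high)))
  }
  fit <- lm(log(value_adj) ~ lu + I(lu^2), data = obs,
            weights = 1 / pmax(obs$design_variance, 1e-6))
  beta <- setNames(coef(fit), c("beta0", "beta1", "beta2"))
  effects <- obs %>%
    mutate(effect = log(.data$value_adj) - (beta[1] + beta[2] * .data$lu + beta[3] * .data$lu^2)) %>%
    select("source", "province", "year", "effect", "design_variance")
  structure(list(coefficients = beta, vcov = vcov(fit),
                 residual_sd = summary(fit)$sigma, effects = effects,
                 drs_completeness = drs_completeness),
            class = "nmr_relation")
}

#' @export
print.nmr_relation <- function(x, ...) {
  cat(sprintf("<nmr_relation> log(NMR) = %.3f + %.3f log(U5MR) + %.3f log(U5MR)^2\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3]))
  invisible(x)
}

#' @export
tidy.nmr_relation <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients),
         std.error = sqrt(diag(x$vcov)))
}

#' @export
glance.nmr_relation <- function(x, ...) {
  tibble(n_effects = nrow(x$effects), residual_sd = x$residual_sd)
}

#' Deterministic NMR surface from a relation
#'
#' Applies `log(NMR) = b0 + b1 log(U5MR) + b2 log(U5MR)^2 + effect` draw-wise
#' to a U5MR surface and truncates each draw at the paired U5MR draw, so
#' NMR <= U5MR holds in every draw by construction.
#'
#' @param coefs numeric `c(beta0, beta1, beta2)` or an `nmr_relation`.
#' @param u5mr_surface a U5MR [rate_surface()].
#' @param effect_surface optional array (province x year x draws, recycled
#'   over draws if a matrix) of additive log-scale effects.
#' @return An NMR [rate_surface()].
#' @export
nmr_from_relation <- function(coefs, u5mr_surface, effect_surface = NULL) {
  if (inherits(coefs, "nmr_relation")) coefs <- coefs$coefficients
  stopifnot(length(coefs) == 3)
  lu <- log(u5mr_surface$draws)
  ln <- coefs[1] + coefs[2] * lu + coefs[3] * lu^2
  if (!is.null(effect_surface)) {
    if (length(dim(effect_surface)) == 2) {
      ln <- ln + as.vector(effect_surface)
    } else {
      ln <- ln + effect_surface
    }
  }
  ln <- pmin(ln, lu) # draw-wise truncation: NMR never exceeds U5MR
  rate_surface(pmin(pmax(exp(ln), 1e-4), 999.9), u5mr_surface$provinces,
               u5mr_surface$years, measure = "NMR", model_tag = "relation")
}

#' Specification for the NMR stage
#'
#' @param gpr a [gpr_spec()] for the effect-surface GP route.
#' @param st an [st_spec()] for the effect-surface spatiotemporal route.
#' @param holdout a [holdout_plan()] for scoring the two effect models.
#' @param weight_method passed to [rank_weights()].
#' @param n_out_draws output draws of the final NMR surface.
#' @param drs_completeness completeness correction for registration NMR values
#'   (under-5 registration completeness is used as a proxy for neonatal
#'   completeness).
#' @param seed master seed of the stage.
#' @return A list of class `nmr_spec`.
#' @export
nmr_spec <- function(gpr = gpr_spec(), st = st_spec(), holdout = holdout_plan(),
                     weight_method = "linear", n_out_draws = 200,
                     drs_completeness = 1, seed = 1) {
  structure(list(gpr = gpr, st = st, holdout = holdout,
                 weight_method = weight_method, n_out_draws = n_out_draws,
                 drs_completeness = drs_completeness, seed = seed),
            class = "nmr_spec")
}

#' Estimate the NMR surface from registration data and a U5MR surface
#'
#' Fits the pooled quadratic log-log relation, models the province-year
#' effects with both stage models (a zero-mean GP with the separable
#' Matérn-time x graph-space kernel, and the BYM + RW2 + interaction
#' spatiotemporal model), weighs the two effect models by out-of-sample rank
#' (RMSE with coverage tie-break) on held-out NMR observations, mixes them,
#' and propagates U5MR posterior uncertainty by pairing each output draw with
#' a U5MR draw and a draw of the quadratic coefficients. Every output draw is
#' truncated at its paired U5MR draw.
#'
#' @param nmr_observations NMR observation tibble.
#' @param u5mr_surface U5MR [rate_surface()].
#' @param adjacency connected province graph.
#' @param spec an [nmr_spec()].
#' @return An object of classes `nmr_fit` and [rate_surface()], with fields
#'   `relation`, `scores`, and `weights`.
#' @export
fit_nmr <- function(nmr_observations, u5mr_surface, adjacency, spec = nmr_spec()) {
  stopifnot(inherits(spec, "nmr_spec"))
  relation <- fit_nmr_relation(nmr_observations, u5mr_surface,
                               drs_completeness = spec$drs_completeness)
  eff <- relation$effects
  provinces <- u5mr_surface$provinces
  years <- u5mr_surface$years
  P <- length(provinces); T_ <- length(years)
  p_idx <- match(eff$province, provinces)
  t_idx <- pmax(1, pmin(T_, round(eff$year) - years[1] + 1))
  cell <- (t_idx - 1L) * P + p_idx

  # GP route for the effects: zero-mean field with the separable kernel
  gs <- spec$gpr
  Ks <- switch(gs$spatial_kernel,
    `adjacency-diffusion` = graph_diffusion_kernel(adjacency, gs$spatial_theta),
    exchangeable = exchangeable_kernel(P, gs$exchangeable_rho)
  )
  Kt <- matern_corr(abs(outer(years, years, "-")), gs$matern_smoothness,
                    gs$length_scale_time)
  dim(Kt) <- c(T_, T_)
  es <- eigen(Ks, symmetric = TRUE); et <- eigen(Kt, symmetric = TRUE)
  lam <- pmax(as.vector(kronecker(et$values, es$values)), 1e-8)
  U <- kronecker(et$vectors, es$vectors)
  Kinv <- U %*% (t(U) / lam)
  gp_fit <- gp_field_engine(
    y = eff$effect, v0 = pmax(eff$design_variance, 1e-8), cell = cell,
    n_cell = P * T_, Kinv = Kinv, source = eff$source,
    ns_scales = gs$nonsampling_sd_prior, adjust = rep(FALSE, nrow(eff)),
    comp_prior = gs$completeness_prior, comp_fixed = NULL,
    amplitude_sd = gs$amplitude_sd, mcmc = gs$mcmc, method = gs$method
  )

  st_fit_eff <- st_field_engine(
    y = eff$effect, v = pmax(eff$design_variance, 1e-8),
    p_idx = p_idx, t_idx = t_idx, P = P, T_ = T_,
    Qs = icar_structure_scaled(adjacency), Qg = rw2_structure(T_), spec = spec$st
  )

  # NMR surfaces implied by each effect model (on the U5MR posterior median),
  # scored against held-out NMR observations
  lu_med <- log(surface_median(u5mr_surface))
  beta <- relation$coefficients
  quad_med <- beta[1] + beta[2] * lu_med + beta[3] * lu_med^2
  implied_surface <- function(field, tag) {
    S <- ncol(field)
    ln <- array(as.vector(quad_med) + field, c(P, T_, S))
    ln <- pmin(ln, array(lu_med, c(P, T_, S)))
    rate_surface(pmin(pmax(exp(ln), 1e-4), 999.9), provinces, years,
                 measure = "NMR", model_tag = tag)
  }
  surf_gp <- implied_surface(gp_fit$field, "GPR")
  surf_st <- implied_surface(st_fit_eff$field, "ST")

  ho <- make_holdout(nmr_observations, spec$holdout)
  scores <- score_models(list(GPR = surf_gp, ST = surf_st), ho$test,
                         drs_completeness = spec$drs_completeness)
  scores <- rank_weights(scores, method = spec$weight_method)

  # mixture of effect fields, then full uncertainty propagation
  with_seed(spec$seed, {
    n_out <- spec$n_out_draws
    w <- scores$weight[match(c("GPR", "ST"), scores$model_tag)]
    pick <- sample.int(2, n_out, replace = TRUE, prob = w)
    fields <- list(gp_fit$field, st_fit_eff$field)
    delta <- vapply(seq_len(n_out), function(s) {
      f <- fields[[pick[s]]]
      f[, sample.int(ncol(f), 1)]
    }, numeric(P * T_))

    n_u5 <- dim(u5mr_surface$draws)[3]
    u5_cols <- ((seq_len(n_out) - 1L) %% n_u5) + 1L
    Rb <- chol(relation$vcov)
    draws <- array(NA_real_, c(P, T_, n_out))
    for (s in seq_len(n_out)) {
      bs <- beta + as.vector(t(Rb) %*% rnorm(3))
      lu <- log(u5mr_surface$draws[, , u5_cols[s]])
      ln <- bs[1] + bs[2] * lu + bs[3] * lu^2 + matrix(delta[, s], P, T_)
      draws[, , s] <- pmin(pmax(exp(pmin(ln, lu)), 1e-4), 999.9)
    }
    out <- rate_surface(draws, provinces, years, measure = "NMR",
                        model_tag = "NMR-BMA", seed = spec$seed)
    out$u5_draw_index <- u5_cols # pairing used for the draw-wise truncation
    out$relation <- relation
    out$scores <- scores
    out$weights <- setNames(w, c("GPR", "ST"))
    class(out) <- c("nmr_fit", class(out))
    out
  })
}

#' @export
glance.nmr_fit <- function(x, ...) {
  tibble(n_draws = dim(x$draws)[3],
         beta0 = x$relation$coefficients[1],
         beta1 = x$relation$coefficients[2],
         beta2 = x$relation$coefficients[3],
         weight_gpr = x$weights["GPR"], weight_st = x$weights["ST"])
}
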