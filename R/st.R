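#' Specification of the spatiotemporal stage model
#'
#' The spatiotemporal model decomposes the log rate into an intercept, a
#' Besag-York-Mollie spatial term (scaled intrinsic-CAR structured effect plus
#' an unstructured province effect), a second-order random-walk (RW2) temporal
#' term — whose null space contains linear trends, so straight-line time
#' trends are unpenalized — and a province-year interaction. Structured
#' effects carry sum-to-zero constraints.
#'
#' @param precision_priors per-component `c(shape, rate)` Gamma hyperpriors on
#'   the precisions: `spatial` (structured CAR), `spatial_iid`, `rw2`,
#'   `interaction`.
#' @param interaction_type `"iid"` (independent province-year effects) or its
#'   synonym `"spaceXtime-type-I"` — the simplest Knorr-Held interaction, an
#'   unstructured effect per cell.
#' @param inference list `method` (`"gibbs"` for blocked Gibbs MCMC — every
#'   conditional is conjugate — or `"laplace"` for an empirical-Bayes mode
#'   with Gaussian draws around it), `chains`, `warmup`, `draws`, `seed`.
#' @param obs_nugget extra observation-level variance added to every design
#'   variance (log scale). The default matches the scale of the non-sampling
#'   variance the GPR stage estimates for registration data, so the two stage
#'   models treat observation noise comparably and the ensemble compares like
#'   with like.
#' @return A list of class `st_spec`.
#' @export
st_spec <- function(precision_priors = list(spatial = c(1, 0.01),
                                            spatial_iid = c(1, 0.01),
                                            rw2 = c(1, 0.005),
                                            interaction = c(1, 0.005)),
                    interaction_type = c("iid", "spaceXtime-type-I"),
                    inference = list(method = "gibbs", chains = 2,
                                     warmup = 200, draws = 150, seed = 1),
                    obs_nugget = 0.015) {
  interaction_type <- match.arg(interaction_type)
  inference <- utils::modifyList(
    list(method = "gibbs", chains = 2, warmup = 200, draws = 150, seed = 1),
    inference)
  if (!inference$method %in% c("gibbs", "laplace")) {
    abort('`inference$method` must be "gibbs" or "laplace"')
  }
  for (nm in names(precision_priors)) {
    pr <- precision_priors[[nm]]
    if (length(pr) != 2 || any(pr <= 0)) abort(sprintf("prior `%s` must be two positive Gamma parameters", nm))
  }
  if (inference$draws < 10) abort("need at least 10 posterior draws")
  structure(list(precision_priors = precision_priors,
                 interaction_type = interaction_type,
                 inference = inference, obs_nugget = obs_nugget),
            class = "st_spec")
}

# ---------------------------------------------------------------------------
# Core Gaussian engine on an arbitrary response y with known variances v.
# Latent x = (alpha, s, u, g, h): intercept, structured spatial, iid spatial,
# RW2 temporal, interaction. Returns draws of eta_cell = alpha+s+u+g+h.
# ---------------------------------------------------------------------------
st_field_engine <- function(y, v, p_idx, t_idx, P, T_, Qs, Qg, spec) {
  n <- length(y)
  m <- 1L + P + P + T_ + P * T_
  i_alpha <- 1L
  i_s <- 1L + seq_len(P)
  i_u <- 1L + P + seq_len(P)
  i_g <- 1L + 2L * P + seq_len(T_)
  i_h <- 1L + 2L * P + T_ + seq_len(P * T_)
  cell <- (t_idx - 1L) * P + p_idx

  A <- sparseMatrix(
    i = rep(seq_len(n), 4),
    j = c(rep(i_alpha, n), i_s[p_idx], i_g[t_idx], i_h[cell]),
    x = 1, dims = c(n, m)
  ) + sparseMatrix(i = seq_len(n), j = i_u[p_idx], x = 1, dims = c(n, m))
  w <- 1 / pmax(v + spec$obs_nugget, 1e-8)
  M <- as.matrix(t(A) %*% Diagonal(x = w) %*% A) # A' W A, fixed across iterations
  b <- as.vector(t(A) %*% (w * y))

  # constraints: sum(s) = 0, sum(g) = 0
  Acon <- matrix(0, 2, m)
  Acon[1, i_s] <- 1
  Acon[2, i_g] <- 1

  pp <- spec$precision_priors
  rank_s <- P - 1; rank_g <- T_ - 2

  prior_prec <- function(tau) {
    Q <- matrix(0, m, m)
    Q[i_alpha, i_alpha] <- 1e-6
    Q[i_s, i_s] <- tau["s"] * Qs
    diag(Q)[i_u] <- tau["u"]
    Q[i_g, i_g] <- tau["g"] * Qg
    diag(Q)[i_h] <- tau["h"]
    # small proper ridge on the intrinsic blocks: their levels are only
    # identified through the sum-to-zero constraints applied below
    diag(Q)[i_s] <- diag(Q)[i_s] + 1e-6
    diag(Q)[i_g] <- diag(Q)[i_g] + 1e-6
    Q
  }

  draw_x <- function(tau, noise = TRUE, n_draw = 1) {
    Ppost <- prior_prec(tau) + M
    R <- tryCatch(chol(Ppost), error = function(e) {
      abort("posterior precision is singular even with sum-to-zero handling; check that the adjacency graph is connected")
    })
    x_mean <- backsolve(R, forwardsolve(t(R), b))
    Z <- if (noise) backsolve(R, matrix(rnorm(m * n_draw), m, n_draw)) else matrix(0, m, n_draw)
    X <- x_mean + Z
    # condition on Acon x = 0 (conditioning by kriging)
    W1 <- backsolve(R, forwardsolve(t(R), t(Acon)))
    S <- Acon %*% W1
    X - W1 %*% solve(S, Acon %*% X)
  }

  tau_update <- function(x, fixed = FALSE) {
    s <- x[i_s]; u <- x[i_u]; g <- x[i_g]; h <- x[i_h]
    shp <- c(s = pp$spatial[1] + rank_s / 2, u = pp$spatial_iid[1] + P / 2,
             g = pp$rw2[1] + rank_g / 2, h = pp$interaction[1] + P * T_ / 2)
    rt <- c(s = pp$spatial[2] + sum(s * (Qs %*% s)) / 2,
            u = pp$spatial_iid[2] + sum(u^2) / 2,
            g = pp$rw2[2] + sum(g * (Qg %*% g)) / 2,
            h = pp$interaction[2] + sum(h^2) / 2)
    if (fixed) pmax((shp - 1), 0.01) / rt else rgamma(4, shape = shp, rate = rt)
  }

  inf <- spec$inference
  eta_of <- function(X) {
    # n_cell x n_draw matrix of alpha + s + u + g + h
    Xs <- X[i_s, , drop = FALSE] + X[i_u, , drop = FALSE]
    out <- X[i_h, , drop = FALSE]
    for (k in seq_len(ncol(X))) {
      out[, k] <- out[, k] + X[i_alpha, k] +
        rep(X[i_g, k], each = P) + rep(Xs[, k], times = T_)
    }
    out
  }

  if (inf$method == "laplace") {
    return(with_seed(inf$seed, {
      tau <- c(s = 10, u = 10, g = 100, h = 100)
      for (it in 1:30) {
        x_mode <- draw_x(tau, noise = FALSE)
        tau <- setNames(tau_update(as.vector(x_mode), fixed = TRUE), c("s", "u", "g", "h"))
      }
      X <- draw_x(tau, noise = TRUE, n_draw = inf$draws)
      list(field = eta_of(X), hyper = tibble(tau_spatial = tau["s"], tau_iid = tau["u"],
                                             tau_rw2 = tau["g"], tau_interaction = tau["h"]),
           rhat = NA_real_, mode = as.vector(x_mode), idx = list(s = i_s, u = i_u, g = i_g, h = i_h, alpha = i_alpha))
    }))
  }

  run_chain <- function(chain_seed) with_seed(chain_seed, {
    tau <- c(s = 10, u = 10, g = 100, h = 100)
    keep_eta <- matrix(NA_real_, P * T_, inf$draws)
    keep_x <- matrix(NA_real_, m, inf$draws)
    keep_tau <- matrix(NA_real_, inf$draws, 4)
    for (it in seq_len(inf$warmup + inf$draws)) {
      x <- as.vector(draw_x(tau))
      tau <- setNames(tau_update(x), c("s", "u", "g", "h"))
      if (it > inf$warmup) {
        k <- it - inf$warmup
        keep_eta[, k] <- eta_of(matrix(x, ncol = 1))
        keep_x[, k] <- x
        keep_tau[k, ] <- tau
      }
    }
    list(eta = keep_eta, x = keep_x, tau = keep_tau)
  })

  chains <- map(seq_len(inf$chains), function(ch) run_chain(inf$seed + 1000 * ch))
  field <- do.call(cbind, map(chains, "eta"))
  xdraws <- do.call(cbind, map(chains, "x"))
  taus <- do.call(rbind, map(chains, "tau"))
  colnames(taus) <- c("tau_spatial", "tau_iid", "tau_rw2", "tau_interaction")

  rh <- NA_real_
  if (inf$chains >= 2) {
    probe <- unique(round(seq(1, P * T_, length.out = min(6, P * T_))))
    rh <- max(vapply(probe, function(j) {
      rhat(do.call(cbind, map(chains, function(o) o$eta[j, ])))
    }, 0), na.rm = TRUE)
    if (is.finite(rh) && rh > 1.05) {
      warn(sprintf("potential non-convergence: max R-hat %.3f > 1.05 over probed cells", rh))
    }
  }
  list(field = field, hyper = as_tibble(taus), rhat = rh, x = xdraws,
       idx = list(s = i_s, u = i_u, g = i_g, h = i_h, alpha = i_alpha))
}

#' Fit the spatiotemporal stage model
#'
#' Posterior draws of the log-rate surface under
#' `log(rate) = intercept + BYM(province) + RW2(year) + interaction`, with a
#' normal likelihood on log observations using their design variances (so the
#' ensemble compares this model with the GPR stage like for like). This stage
#' does not model registration completeness; pass completeness-corrected
#' registration values (the pipeline divides DRS values by the GPR posterior
#' mean completeness).
#'
#' @param observations observation tibble, one measure.
#' @param adjacency connected province graph; vertices define the surface.
#' @param spec an [st_spec()].
#' @param years optional explicit contiguous year grid.
#' @return An object of classes `st_fit` and [rate_surface()], with `hyper`
#'   (precision draws) and `diagnostics`.
#' @export
fit_st <- function(observations, adjacency, spec = st_spec(), years = NULL) {
  stopifnot(inherits(spec, "st_spec"))
  validate_observations(observations)
  if (!igraph::is_connected(adjacency)) abort("adjacency graph must be connected")
  ms <- unique(observations$measure)
  if (length(ms) != 1) abort("fit one measure at a time")
  obs <- observations %>% filter(.data$value > 0)
  provinces <- igraph::V(adjacency)$name
  if (!all(obs$province %in% provinces)) {
    abort("observations reference provinces absent from the adjacency graph")
  }
  years <- years %||% seq(floor(min(obs$year)), ceiling(max(obs$year)))
  if (!all(diff(years) == 1)) abort("`years` must be contiguous")
  P <- length(provinces); T_ <- length(years)
  p_idx <- match(obs$province, provinces)
  t_idx <- pmax(1, pmin(T_, round(obs$year) - years[1] + 1))

  Qs <- icar_structure_scaled(adjacency)
  Qg <- rw2_structure(T_)

  fit <- st_field_engine(log(obs$value), pmax(obs$design_variance, 1e-8),
                         p_idx, t_idx, P, T_, Qs, Qg, spec)
  S <- ncol(fit$field)
  draws <- pmin(pmax(exp(array(fit$field, c(P, T_, S))), 1e-4), 999.9)
  out <- rate_surface(draws, provinces, years, measure = ms,
                      model_tag = "ST", seed = spec$inference$seed)
  out$hyper <- fit$hyper
  out$diagnostics <- list(rhat = fit$rhat, method = spec$inference$method)
  out$spec <- spec
  out$latent <- fit[c("x", "idx", "mode")]
  class(out) <- c("st_fit", class(out))
  out
}

#' @export
glance.st_fit <- function(x, ...) {
  tibble(measure = x$measure, n_draws = dim(x$draws)[3],
         method = x$diagnostics$method, max_rhat = x$diagnostics$rhat,
         mean_sd_spatial = mean(1 / sqrt(x$hyper$tau_spatial)),
         mean_sd_rw2 = mean(1 / sqrt(x$hyper$tau_rw2)))
}
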