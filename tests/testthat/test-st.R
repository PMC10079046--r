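test_that("the RW2 null space reproduces a linear time trend exactly", {
  # one graph, constant-in-space truth declining linearly on the log scale:
  # with spatial and interaction variation absent, the fitted surface must
  # match the line because linear trends are unpenalized under RW2
  g <- make_adjacency(4, "ring")
  years <- 2010:2017
  line <- 3.2 - 0.05 * (years - 2010)
  obs <- tidyr::crossing(province = igraph::V(g)$name, year = years) %>%
    dplyr::mutate(source = "CBH", measure = "U5MR", value = exp(line[year - 2009]),
                  design_variance = 1e-8, completeness_adjustable = FALSE,
                  completeness = NA_real_)
  fit <- fit_st(obs, g, st_spec(inference = list(method = "laplace", draws = 50,
                                                 seed = 1), obs_nugget = 0),
                years = years)
  med <- log(surface_median(fit))
  for (p in 1:4) expect_equal(unname(med[p, ]), line, tolerance = 1e-3)
})

test_that("CAR conditional mean equals the neighbour average on a 4-node graph", {
  g <- igraph::graph_from_literal(A - B, B - C, C - D, A - C) # 4 nodes, mixed degrees
  Q <- sdgmort:::icar_structure(g)
  x <- c(0.3, -0.1, 0.4, -0.6)
  for (i in 1:4) {
    cond_mean <- -sum(Q[i, -i] * x[-i]) / Q[i, i] # brute force from the joint precision
    nbrs <- which(Q[i, ] != 0)
    nbrs <- setdiff(nbrs, i)
    expect_equal(cond_mean, mean(x[nbrs]), tolerance = 1e-12)
  }
})

test_that("structured effects satisfy their sum-to-zero constraints draw-wise", {
  truth <- generate_truth(synth_config(n_provinces = 6, years = 2010:2016, seed = 3))
  obs <- exact_observations(truth, design_variance = 0.01)
  fit <- fit_st(obs, truth$adjacency, smoke_st(4), years = truth$years)
  x <- fit$latent$x
  idx <- fit$latent$idx
  expect_lt(max(abs(colSums(x[idx$s, ]))), 1e-8)
  expect_lt(max(abs(colSums(x[idx$g, ]))), 1e-8)
})

test_that("the posterior mode solves the penalized least-squares problem", {
  g <- igraph::make_ring(3)
  igraph::V(g)$name <- c("A", "B", "C")
  years <- 2011:2014
  set.seed(9)
  obs <- tidyr::crossing(province = c("A", "B", "C"), year = years) %>%
    dplyr::mutate(source = "CBH", measure = "U5MR",
                  value = exp(rnorm(dplyr::n(), 3, 0.2)),
                  design_variance = 0.05, completeness_adjustable = FALSE,
                  completeness = NA_real_)
  spec <- st_spec(inference = list(method = "laplace", draws = 20, seed = 2),
                  obs_nugget = 0)
  fit <- fit_st(obs, g, spec, years = years)
  tau <- c(s = unname(fit$hyper$tau_spatial[1]), u = unname(fit$hyper$tau_iid[1]),
           g = unname(fit$hyper$tau_rw2[1]), h = unname(fit$hyper$tau_interaction[1]))

  # independent oracle: solve the same penalized problem via the KKT system
  P_ <- 3; T_ <- length(years)
  m <- 1 + P_ + P_ + T_ + P_ * T_
  i_s <- 1 + 1:P_; i_u <- 1 + P_ + 1:P_; i_g <- 1 + 2 * P_ + 1:T_
  i_h <- 1 + 2 * P_ + T_ + 1:(P_ * T_)
  p_idx <- match(obs$province, c("A", "B", "C"))
  t_idx <- obs$year - 2010
  cell <- (t_idx - 1) * P_ + p_idx
  A <- matrix(0, nrow(obs), m)
  for (r in seq_len(nrow(obs))) {
    A[r, 1] <- 1; A[r, i_s[p_idx[r]]] <- 1; A[r, i_u[p_idx[r]]] <- 1
    A[r, i_g[t_idx[r]]] <- 1; A[r, i_h[cell[r]]] <- 1
  }
  Qs <- sdgmort:::icar_structure_scaled(g)
  Qg <- sdgmort:::rw2_structure(T_)
  Q <- matrix(0, m, m)
  Q[1, 1] <- 1e-6
  Q[i_s, i_s] <- tau["s"] * Qs; diag(Q)[i_u] <- tau["u"]
  Q[i_g, i_g] <- tau["g"] * Qg; diag(Q)[i_h] <- tau["h"]
  diag(Q)[c(i_s, i_g)] <- diag(Q)[c(i_s, i_g)] + 1e-6
  W <- diag(1 / obs$design_variance)
  Acon <- matrix(0, 2, m); Acon[1, i_s] <- 1; Acon[2, i_g] <- 1
  kkt <- rbind(cbind(t(A) %*% W %*% A + Q, t(Acon)),
               cbind(Acon, matrix(0, 2, 2)))
  rhs <- c(t(A) %*% W %*% log(obs$value), 0, 0)
  x_star <- solve(kkt, rhs)[1:m]
  eta_star <- x_star[1] + x_star[i_s][p_idx] + x_star[i_u][p_idx] +
    x_star[i_g][t_idx] + x_star[i_h][cell]

  eta_fit <- fit$latent$mode[1] + fit$latent$mode[i_s][p_idx] +
    fit$latent$mode[i_u][p_idx] + fit$latent$mode[i_g][t_idx] +
    fit$latent$mode[i_h][cell]
  expect_equal(eta_fit, eta_star, tolerance = 1e-6)
})

test_that("component variances are recovered within two posterior SDs on average", {
  n_rep <- 20
  sd_true <- c(s = 0.20, g = 0.10, h = 0.06)
  post_mean <- matrix(NA_real_, n_rep, 3)
  post_sd <- matrix(NA_real_, n_rep, 3)
  g <- make_adjacency(8, "grid")
  P_ <- 8; T_ <- 10; years <- 2008:2017
  Qs <- sdgmort:::icar_structure_scaled(g)
  for (r in seq_len(n_rep)) {
    set.seed(400 + r)
    s <- as.vector(sdgmort:::sample_constrained_gmrf(Qs, sd_true["s"]))
    gt <- numeric(T_)
    for (t in 3:T_) gt[t] <- 2 * gt[t - 1] - gt[t - 2] + rnorm(1, 0, sd_true["g"])
    gt <- gt - mean(gt)
    h <- rnorm(P_ * T_, 0, sd_true["h"])
    eta <- 3 + rep(s, T_) + rep(gt, each = P_) + h
    obs <- tibble::tibble(
      source = "CBH",
      province = rep(igraph::V(g)$name, T_),
      year = rep(years, each = P_),
      measure = "U5MR",
      value = exp(eta + rnorm(P_ * T_, 0, 0.03)),
      design_variance = 0.03^2,
      completeness_adjustable = FALSE, completeness = NA_real_
    )
    fit <- suppressWarnings(
      fit_st(obs, g, st_spec(inference = list(chains = 2, warmup = 100,
                                              draws = 100, seed = 400 + r),
                             obs_nugget = 0), years = years)
    )
    sds <- cbind(1 / sqrt(fit$hyper$tau_spatial), 1 / sqrt(fit$hyper$tau_rw2),
                 1 / sqrt(fit$hyper$tau_interaction))
    post_mean[r, ] <- colMeans(sds)
    post_sd[r, ] <- apply(sds, 2, sd)
  }
  for (k in 1:3) {
    expect_lt(abs(mean(post_mean[, k]) - sd_true[k]), 2 * mean(post_sd[, k]))
  }
})

test_that("spatiotemporal fits are seed-reproducible", {
  truth <- generate_truth(synth_config(n_provinces = 5, years = 2012:2016, seed = 6))
  obs <- exact_observations(truth, design_variance = 0.02)
  spec <- st_spec(inference = list(chains = 2, warmup = 30, draws = 30, seed = 11))
  f1 <- fit_st(obs, truth$adjacency, spec, years = truth$years)
  f2 <- fit_st(obs, truth$adjacency, spec, years = truth$years)
  expect_identical(f1$draws, f2$draws)
})
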