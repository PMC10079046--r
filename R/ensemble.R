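#' Holdout plan for out-of-sample model scoring
#'
#' The ensemble weighs stage models by out-of-sample performance: a random
#' 20% of registration (DRS) observations and 20% of all other observations
#' are held back as test data.
#'
#' @param frac_drs,frac_other held-out fractions per stratum, in (0, 1).
#' @param seed RNG seed for the partition.
#' @return A list of class `holdout_plan`.
#' @export
holdout_plan <- function(frac_drs = 0.20, frac_other = 0.20, seed = 1) {
  for (f in c(frac_drs, frac_other)) {
    if (!is.numeric(f) || f <= 0 || f >= 1) abort("holdout fractions must lie in (0, 1)")
  }
  structure(list(frac_drs = frac_drs, frac_other = frac_other, seed = seed),
            class = "holdout_plan")
}

#' @rdname holdout_plan
#' @param observations observation tibble.
#' @param plan a `holdout_plan`.
#' @return `make_holdout()`: a list with disjoint `train` and `test` tibbles
#'   whose union is `observations`; the per-stratum held-out count is
#'   `round(frac * n)` (never less than 1). Identical seeds give identical
#'   partitions.
#' @export
make_holdout <- function(observations, plan = holdout_plan()) {
  validate_observations(observations)
  is_drs <- observations$source == "DRS"
  pick <- function(idx, frac) {
    n <- length(idx)
    if (n == 0) return(integer(0))
    if (n < 2) abort("a holdout stratum has fewer than 2 observations")
    k <- max(1L, round(frac * n))
    if (k >= n) abort("a holdout stratum is too small for the requested fraction")
    sample(idx, k)
  }
  with_seed(plan$seed, {
    test_idx <- c(pick(which(is_drs), plan$frac_drs),
                  pick(which(!is_drs), plan$frac_other))
    list(train = observations[-test_idx, , drop = FALSE],
         test = observations[sort(test_idx), , drop = FALSE])
  })
}

# posterior median / interval of a surface at given (province, year) points
surface_at <- function(surface, province, year) {
  p <- match(province, surface$provinces)
  t <- pmax(1, pmin(length(surface$years), round(year) - surface$years[1] + 1))
  if (anyNA(p)) abort("surface does not cover all test provinces")
  med <- apply(surface$draws, c(1, 2), median)
  lo <- apply(surface$draws, c(1, 2), quantile, probs = 0.025)
  hi <- apply(surface$draws, c(1, 2), quantile, probs = 0.975)
  idx <- cbind(p, t)
  tibble(median = med[idx], lower95 = lo[idx], upper95 = hi[idx])
}

#' Score stage models on held-out observations
#'
#' RMSE is the root-mean-square of `log(observed) - log(posterior median)`
#' over test points, with registration test values completeness-corrected
#' (divided by `drs_completeness`) before comparison; `coverage95` is the
#' fraction of test points inside the 95% posterior interval. Models are
#' ranked by RMSE ascending with `|coverage95 - 0.95|` as tie-break (or by
#' the rank-sum of both metrics with `ranking = "rank-sum"`).
#'
#' @param surfaces named list of [rate_surface()]s (names are model tags).
#' @param test held-out observation tibble.
#' @param drs_completeness completeness used to correct DRS test values.
#' @param ranking `"rmse"` or `"rank-sum"`.
#' @return A tibble `model_tag`, `rmse`, `coverage95`, `rank`.
#' @export
score_models <- function(surfaces, test, drs_completeness = 1, ranking = c("rmse", "rank-sum")) {
  ranking <- match.arg(ranking)
  if (nrow(test) == 0) abort("empty test set")
  if (is.null(names(surfaces)) || any(names(surfaces) == "")) {
    names(surfaces) <- vapply(surfaces, function(s) s$model_tag, "")
  }
  adj <- if (is.null(test$completeness_adjustable)) rep(FALSE, nrow(test)) else isTRUE_vec(test$completeness_adjustable)
  value <- test$value / ifelse(adj, drs_completeness, 1)
  keep <- value > 0
  scores <- imap(surfaces, function(surf, tag) {
    at <- surface_at(surf, test$province, test$year)
    resid <- log(value[keep]) - log(at$median[keep])
    tibble(model_tag = tag,
           rmse = sqrt(mean(resid^2)),
           coverage95 = mean(value[keep] >= at$lower95[keep] & value[keep] <= at$upper95[keep]))
  }) %>% list_rbind()
  if (ranking == "rmse") {
    ord <- order(scores$rmse, abs(scores$coverage95 - 0.95), scores$model_tag)
  } else {
    rs <- rank(scores$rmse) + rank(abs(scores$coverage95 - 0.95))
    ord <- order(rs, scores$rmse, scores$model_tag)
  }
  scores$rank <- integer(nrow(scores))
  scores$rank[ord] <- seq_len(nrow(scores))
  arrange(scores, .data$rank)
}

#' Rank-based ensemble weights
#'
#' A monotonically declining function of model rank: by default
#' `weight_k` is proportional to `K - rank_k + 1` (reverse rank); the
#' exponential alternative uses `exp(-lambda * rank)`. Weights sum to 1 and
#' strictly decrease in rank.
#'
#' @param scores a [score_models()] tibble (needs `rank`).
#' @param method `"linear"` or `"exponential"`.
#' @param lambda decline rate of the exponential variant.
#' @return `scores` with a `weight` column added.
#' @export
rank_weights <- function(scores, method = c("linear", "exponential"), lambda = 1) {
  method <- match.arg(method)
  K <- nrow(scores)
  if (!setequal(scores$rank, seq_len(K))) abort("`rank` must be a permutation of 1..K")
  w <- switch(method,
    linear = K - scores$rank + 1,
    exponential = exp(-lambda * scores$rank)
  )
  scores$weight <- w / sum(w)
  scores
}

#' Bayesian-model-averaged surface
#'
#' Draws of the combined posterior are sampled from the mixture of the stage
#' models' posteriors: each output draw comes from model `k` with probability
#' `weight_k`.
#'
#' @param surfaces named list of aligned [rate_surface()]s.
#' @param weights numeric weights (normalized internally) in the order of
#'   `surfaces`, or a [rank_weights()] tibble matched by `model_tag`.
#' @param n_out_draws number of output draws (default: draws of the first
#'   surface).
#' @param seed RNG seed.
#' @return A [rate_surface()] with `model_tag = "BMA"`.
#' @export
combine_surfaces <- function(surfaces, weights, n_out_draws = NULL, seed = 1) {
  if (is.data.frame(weights)) {
    if (is.null(names(surfaces))) names(surfaces) <- vapply(surfaces, function(s) s$model_tag, "")
    weights <- weights$weight[match(names(surfaces), weights$model_tag)]
  }
  if (length(weights) != length(surfaces) || anyNA(weights)) {
    abort("need one weight per surface")
  }
  if (any(weights < 0)) abort("weights must be non-negative")
  weights <- weights / sum(weights)
  ref <- surfaces[[1]]
  for (s in surfaces[-1]) {
    if (!identical(s$provinces, ref$provinces) || !identical(s$years, ref$years) ||
        !identical(s$measure, ref$measure)) {
      abort("surfaces are not aligned (provinces/years/measure mismatch)")
    }
  }
  n_out <- n_out_draws %||% dim(ref$draws)[3]
  with_seed(seed, {
    pick <- sample.int(length(surfaces), n_out, replace = TRUE, prob = weights)
    draws <- array(NA_real_, c(length(ref$provinces), length(ref$years), n_out))
    for (k in seq_along(surfaces)) {
      sel <- which(pick == k)
      if (!length(sel)) next
      src <- surfaces[[k]]$draws
      cols <- sample.int(dim(src)[3], length(sel), replace = TRUE)
      draws[, , sel] <- src[, , cols, drop = FALSE]
    }
    out <- rate_surface(draws, ref$provinces, ref$years, measure = ref$measure,
                        model_tag = "BMA", seed = seed)
    out$weights <- setNames(weights, names(surfaces))
    out
  })
}
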