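# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so seeded operations never perturb the global stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

stop_if_not_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be positive.", name))
  invisible(x)
}

# deaths-per-1000 <-> log scale with a guard against zeros
log_rate <- function(value) {
  if (any(value <= 0)) abort("rates must be positive before taking logs")
  log(value)
}

# split-chain style potential scale reduction on a draws matrix (iter x chain)
rhat <- function(x) {
  x <- as.matrix(x)
  m <- ncol(x)
  n <- nrow(x)
  if (m < 2 || n < 4) return(NA_real_)
  chain_means <- colMeans(x)
  b <- n * var(chain_means)
  w <- mean(apply(x, 2, var))
  if (w <= 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}
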