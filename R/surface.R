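#' Posterior rate surfaces
#'
#' A `rate_surface` holds posterior draws of a latent mortality rate (deaths per
#' 1,000 live births) on a province-by-year panel. Stage models
#' ([fit_gpr()], [fit_st()]), the ensemble ([combine_surfaces()]) and the NMR
#' relation ([fit_nmr()]) all return this container, so every downstream
#' summary, metric and plot works on any of them.
#'
#' @param draws numeric array `provinces x years x draws` of rates per 1,000.
#' @param provinces character vector of province labels.
#' @param years integer vector of calendar years.
#' @param measure `"U5MR"` or `"NMR"`.
#' @param model_tag short label identifying the producing model.
#' @param seed the RNG seed the draws were generated under.
#'
#' @return An object of class `rate_surface`.
#' @export
rate_surface <- function(draws, provinces, years, measure = "U5MR",
                         model_tag = "surface", seed = NA_integer_) {
  draws <- as.array(draws)
  if (length(dim(draws)) != 3) abort("`draws` must be a 3-d array (province x year x draw)")
  if (dim(draws)[1] != length(provinces) || dim(draws)[2] != length(years)) {
    abort("`draws` dimensions do not match `provinces` / `years`")
  }
  if (!all(is.finite(draws))) abort("rate draws must be finite")
  if (any(draws <= 0) || any(draws >= 1000)) {
    abort("rate draws must lie in (0, 1000) deaths per 1,000 live births")
  }
  dimnames(draws) <- list(provinces, years, NULL)
  structure(
    list(draws = draws, provinces = as.character(provinces),
         years = as.integer(years), measure = measure,
         model_tag = model_tag, seed = seed),
    class = "rate_surface"
  )
}

#' @export
print.rate_surface <- function(x, ...) {
  cat(sprintf("<rate_surface> %s [%s]: %d provinces x %d years x %d draws\n",
              x$measure, x$model_tag, length(x$provinces), length(x$years),
              dim(x$draws)[3]))
  invisible(x)
}

#' Posterior summary of a rate surface
#'
#' @param object a [rate_surface()].
#' @param probs interval probabilities; default gives the 95% credible interval.
#' @param ... unused.
#' @return A tibble with one row per province-year: `median`, `lower95`,
#'   `upper95`.
#' @export
summary.rate_surface <- function(object, probs = c(0.025, 0.975), ...) {
  med <- apply(object$draws, c(1, 2), median)
  lo <- apply(object$draws, c(1, 2), quantile, probs = probs[1])
  hi <- apply(object$draws, c(1, 2), quantile, probs = probs[2])
  tibble(
    province = rep(object$provinces, each = length(object$years)),
    year = rep(object$years, times = length(object$provinces)),
    measure = object$measure,
    median = as.vector(t(med)),
    lower95 = as.vector(t(lo)),
    upper95 = as.vector(t(hi))
  )
}

#' Long-format draws of a rate surface
#'
#' @param x a [rate_surface()].
#' @param ... unused.
#' @return A tibble `province`, `year`, `draw`, `value`.
#' @export
tidy.rate_surface <- function(x, ...) {
  n_draw <- dim(x$draws)[3]
  tibble(
    province = rep(x$provinces, times = length(x$years) * n_draw),
    year = rep(rep(x$years, each = length(x$provinces)), times = n_draw),
    draw = rep(seq_len(n_draw), each = length(x$provinces) * length(x$years)),
    value = as.vector(x$draws)
  )
}

#' @export
glance.rate_surface <- function(x, ...) {
  tibble(measure = x$measure, model_tag = x$model_tag,
         n_provinces = length(x$provinces), n_years = length(x$years),
         n_draws = dim(x$draws)[3], seed = x$seed)
}

#' Province-by-year matrix of posterior medians
#'
#' @param surface a [rate_surface()].
#' @return A numeric matrix (provinces x years).
#' @export
surface_median <- function(surface) {
  apply(surface$draws, c(1, 2), median)
}

#' Write / read a rate surface as long-format CSV
#'
#' The on-disk format is one row per (province, year, draw) with the rate in
#' deaths per 1,000 live births, so surfaces round-trip between sessions and
#' external tools.
#'
#' @param surface a [rate_surface()].
#' @param path CSV file path.
#' @return `write_surface()` returns `path` invisibly; `read_surface()` returns
#'   a [rate_surface()].
#' @export
write_surface <- function(surface, path) {
  df <- tidy(surface)
  df$measure <- surface$measure
  df$model_tag <- surface$model_tag
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_surface
#' @param measure,model_tag metadata applied when absent from the file.
#' @export
read_surface <- function(path, measure = NULL, model_tag = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("province", "year", "draw", "value")
  miss <- setdiff(needed, names(df))
  if (length(miss)) abort(sprintf("surface CSV lacks columns: %s", paste(miss, collapse = ", ")))
  provinces <- sort(unique(df$province))
  years <- sort(unique(df$year))
  draws_ids <- sort(unique(df$draw))
  arr <- array(NA_real_, c(length(provinces), length(years), length(draws_ids)),
               dimnames = list(provinces, years, NULL))
  arr[cbind(match(df$province, provinces), match(df$year, years),
            match(df$draw, draws_ids))] <- df$value
  if (anyNA(arr)) abort("surface CSV does not cover the full province x year x draw grid")
  rate_surface(arr, provinces, years,
               measure = measure %||% df$measure[1] %||% "U5MR",
               model_tag = model_tag %||% df$model_tag[1] %||% "surface")
}
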