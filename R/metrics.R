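#' Neonatal share of under-5 mortality
#'
#' `100 * NMR / U5MR`. For plain numbers the share is returned directly; for
#' a pair of aligned [rate_surface()]s it is computed draw-wise and summarized
#' by median and 95% interval per province-year. Because NMR surfaces are
#' truncated at U5MR draw-wise, surface shares never exceed 100%.
#'
#' @param nmr,u5mr numeric vectors, or aligned [rate_surface()]s.
#' @return A numeric vector, or a tibble `province`, `year`, `share`,
#'   `lower95`, `upper95`.
#' @export
neonatal_share <- function(nmr, u5mr) {
  if (inherits(nmr, "rate_surface")) {
    if (!inherits(u5mr, "rate_surface") ||
        !identical(nmr$provinces, u5mr$provinces) ||
        !identical(nmr$years, u5mr$years)) {
      abort("surfaces are misaligned")
    }
    n_draw <- min(dim(nmr$draws)[3], dim(u5mr$draws)[3])
    share <- 100 * nmr$draws[, , seq_len(n_draw), drop = FALSE] /
      u5mr$draws[, , seq_len(n_draw), drop = FALSE]
    med <- apply(share, c(1, 2), median)
    lo <- apply(share, c(1, 2), quantile, probs = 0.025)
    hi <- apply(share, c(1, 2), quantile, probs = 0.975)
    return(tibble(
      province = rep(nmr$provinces, each = length(nmr$years)),
      year = rep(nmr$years, times = length(nmr$provinces)),
      share = as.vector(t(med)), lower95 = as.vector(t(lo)),
      upper95 = as.vector(t(hi))
    ))
  }
  100 * nmr / u5mr
}

#' Provincial range of a rate column
#'
#' @param panel a data frame with an area/province label column and the rate
#'   column of interest.
#' @param col name of the rate column.
#' @param label name of the label column.
#' @return A one-row tibble: `max`, `min`, `diff`, `argmax`, `argmin`.
#' @export
provincial_range <- function(panel, col, label = "area") {
  if (nrow(panel) < 2) abort("need at least 2 provinces")
  v <- panel[[col]]
  lab <- panel[[label]]
  tibble(max = max(v), min = min(v), diff = max(v) - min(v),
         argmax = lab[which.max(v)], argmin = lab[which.min(v)])
}

#' Count provinces above the SDG threshold
#'
#' Uses a strict inequality: provinces exactly at the threshold count as
#' having achieved it.
#'
#' @param panel data frame of provincial rates.
#' @param col rate column name.
#' @param threshold SDG threshold (deaths per 1,000).
#' @param label label column name.
#' @return A list: `count` and `provinces` (those strictly above).
#' @export
sdg_count <- function(panel, col, threshold = 12, label = "area") {
  above <- panel[[col]] > threshold
  list(count = sum(above), provinces = panel[[label]][above])
}

#' Live-birth-weighted national aggregate of a surface
#'
#' @param surface a [rate_surface()].
#' @param live_births tibble `province`, `births` (constant weights) or
#'   `province`, `year`, `births`.
#' @return A [rate_surface()] with the single area `"National"`.
#' @export
national_aggregate <- function(surface, live_births) {
  P <- length(surface$provinces); T_ <- length(surface$years)
  if ("year" %in% names(live_births)) {
    w <- matrix(NA_real_, P, T_)
    idx <- cbind(match(live_births$province, surface$provinces),
                 match(live_births$year, surface$years))
    ok <- complete.cases(idx)
    w[idx[ok, , drop = FALSE]] <- live_births$births[ok]
    if (anyNA(w)) abort("live births do not cover the full surface grid")
  } else {
    b <- live_births$births[match(surface$provinces, live_births$province)]
    if (anyNA(b)) abort("live births do not cover all provinces")
    w <- matrix(b, P, T_)
  }
  S <- dim(surface$draws)[3]
  nat <- array(NA_real_, c(1, T_, S))
  for (t in seq_len(T_)) {
    slice <- matrix(surface$draws[, t, ], nrow = P)
    nat[1, t, ] <- colSums(slice * w[, t]) / sum(w[, t])
  }
  rate_surface(nat, "National", surface$years, measure = surface$measure,
               model_tag = paste0(surface$model_tag, "-national"))
}

#' Table-style panel summary
#'
#' Builds the standard reporting table from provincial point estimates in two
#' reference years: AARRs in percent, neonatal share in the later year, and
#' rate ranks (1 = lowest rate; ties broken by label). Internal arithmetic is
#' full precision; rounding to one decimal happens only in the returned
#' display columns (suffixed `_1dp`).
#'
#' @param panel tibble with columns `area`, `u5mr_2010`, `u5mr_2017`,
#'   `nmr_2010`, `nmr_2017` (any two reference years; names follow the
#'   `measure_year` pattern).
#' @param t1,t2 the two reference years in the column names.
#' @return `panel` with `u5mr_aarr_pct`, `nmr_aarr_pct`, `share_t2`,
#'   rank columns and one-decimal display columns added.
#' @export
panel_summary <- function(panel, t1 = 2010, t2 = 2017) {
  c1 <- function(m) sprintf("%s_%d", m, t1)
  c2 <- function(m) sprintf("%s_%d", m, t2)
  for (cc in c(c1("u5mr"), c2("u5mr"), c1("nmr"), c2("nmr"))) {
    if (!cc %in% names(panel)) abort(sprintf("panel lacks column `%s`", cc))
  }
  rank_by <- function(v, lab) order(order(v, lab)) # 1 = lowest rate; ties by label
  out <- panel %>%
    mutate(
      u5mr_aarr_pct = 100 * arr(.data[[c1("u5mr")]], .data[[c2("u5mr")]], t1, t2),
      nmr_aarr_pct = 100 * arr(.data[[c1("nmr")]], .data[[c2("nmr")]], t1, t2),
      share_t2 = neonatal_share(.data[[c2("nmr")]], .data[[c2("u5mr")]])
    )
  out$nmr_rank_t1 <- rank_by(panel[[c1("nmr")]], panel$area)
  out$nmr_rank_t2 <- rank_by(panel[[c2("nmr")]], panel$area)
  out$u5mr_aarr_pct_1dp <- round_half_up(out$u5mr_aarr_pct, 1)
  out$nmr_aarr_pct_1dp <- round_half_up(out$nmr_aarr_pct, 1)
  out$share_t2_1dp <- round_half_up(out$share_t2, 1)
  out
}

#' Published national and provincial rates, 2010 and 2017
#'
#' The published point estimates (medians) of U5MR and NMR per 1,000 live
#' births in 2010 and 2017 with their average ARRs in percent, for the
#' national level, the four regions, and the 31 provinces. Bundled as a
#' plain CSV and used as printed inputs for the arithmetic reproduction
#' checks and the scenario projections.
#'
#' @param level optionally filter to `"national"`, `"region"` or
#'   `"province"`.
#' @return A tibble `level`, `area`, `u5mr_2010`, `u5mr_2017`,
#'   `u5mr_aarr_pct`, `nmr_2010`, `nmr_2017`, `nmr_aarr_pct`.
#' @export
iran_mortality <- function(level = NULL) {
  path <- system.file("extdata", "iran_mortality_2010_2017.csv", package = "sdgmort")
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE, check.names = FALSE))
  if (!is.null(level)) df <- df[df$level %in% level, , drop = FALSE]
  df
}
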