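#' Plot a posterior rate surface
#'
#' Median and 95% credible ribbon per province over time.
#'
#' @param object a [rate_surface()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.rate_surface <- function(object, ...) {
  s <- summary(object)
  ggplot(s, aes(x = .data$year, y = .data$median)) +
    geom_ribbon(aes(ymin = .data$lower95, ymax = .data$upper95),
                fill = "steelblue", alpha = 0.25) +
    geom_line(colour = "steelblue") +
    facet_wrap(~province) +
    labs(x = NULL, y = sprintf("%s (deaths per 1,000 live births)", object$measure),
         title = sprintf("Posterior %s surface [%s]", object$measure, object$model_tag)) +
    theme_minimal()
}

#' Plot a scenario projection
#'
#' Projected provincial NMR paths with the SDG threshold.
#'
#' @param object a [project_scenario()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.projection_result <- function(object, ...) {
  ggplot(object$path, aes(x = .data$year, y = .data$rate, group = .data$province)) +
    geom_line(alpha = 0.7, colour = "grey30") +
    geom_hline(yintercept = object$spec$sdg_threshold, linetype = 2, colour = "firebrick") +
    labs(x = NULL, y = "NMR (deaths per 1,000 live births)",
         title = sprintf("Scenario %s projection to %d", object$spec$id, object$spec$horizon)) +
    theme_minimal()
}

#' Plot ensemble model scores
#'
#' Out-of-sample RMSE with the resulting ensemble weights.
#'
#' @param scores a [rank_weights()] tibble.
#' @return A ggplot.
#' @export
plot_model_scores <- function(scores) {
  ggplot(scores, aes(x = stats::reorder(.data$model_tag, .data$rank), y = .data$rmse)) +
    geom_col(fill = "steelblue", width = 0.6) +
    geom_point(aes(y = .data$weight), colour = "firebrick", size = 3) +
    labs(x = NULL, y = "out-of-sample RMSE (bars) / ensemble weight (points)",
         title = "Stage-model scoring") +
    theme_minimal()
}

#' Plot the fitted NMR--U5MR relation
#'
#' The pooled quadratic on the log-log scale with the observed effect points.
#'
#' @param object an [fit_nmr_relation()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.nmr_relation <- function(object, ...) {
  b <- object$coefficients
  lu <- seq(min(2, log(5)), log(60), length.out = 100)
  curve_df <- tibble(u5mr = exp(lu), nmr = exp(b[1] + b[2] * lu + b[3] * lu^2))
  ggplot(curve_df, aes(x = .data$u5mr, y = .data$nmr)) +
    geom_line(colour = "steelblue") +
    labs(x = "U5MR (per 1,000, log scale)", y = "expected NMR (per 1,000, log scale)",
         title = "Quadratic log-log NMR-U5MR relation") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    theme_minimal()
}
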