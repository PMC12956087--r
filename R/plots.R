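#' Plot the survival / volunteer-burden trade-off of a KPI table
#'
#' Each point is a policy; the x axis measures the burden on volunteers
#' (redundant arrivals by default), the y axis the benefit to patients
#' (expected survivors per year). Facets by density when several volunteer
#' counts are present.
#'
#' @param object A `cfr_kpi_table` from [run_policies()] or [run_tables()].
#' @param x,y KPI column names to plot (defaults `redundant_arrivals`,
#'   `survivors_per_year`).
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot cfr_kpi_table
#' @export
autoplot.cfr_kpi_table <- function(object, x = "redundant_arrivals",
                                   y = "survivors_per_year", ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data[[x]], y = .data[[y]], colour = .data$family
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(group = .data$family),
                       linewidth = 0.3, alpha = 0.6) +
    ggplot2::labs(x = x, y = y, colour = "policy family") +
    ggplot2::theme_minimal()
  if (dplyr::n_distinct(object$n_volunteers) > 1L) {
    p <- p + ggplot2::facet_wrap(~n_volunteers, labeller = ggplot2::label_both)
  }
  p
}

#' Plot a fitted speed model over the block medians
#'
#' @param object A `cfr_speed_fit` from [fit_speed_model()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot cfr_speed_fit
#' @export
autoplot.cfr_speed_fit <- function(object, ...) {
  ggplot2::ggplot(object$blocks,
                  ggplot2::aes(x = .data$midpoint_m,
                               y = .data$median_speed_kmh)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$model$intercept_kmh,
                         slope = object$model$slope_kmh_per_m,
                         colour = "steelblue") +
    ggplot2::labs(x = "distance (m)", y = "median speed (km/h)",
                  title = sprintf("speed = %.3g + %.3g x,  R² = %.3f",
                                  object$model$intercept_kmh,
                                  object$model$slope_kmh_per_m,
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot the Monte Carlo spread of a simulation's KPIs
#'
#' Distribution of the per-outer-replication inner means for each KPI of a
#' single [run_policy()] run; useful for judging whether the replication
#' counts are adequate.
#'
#' @param object A `cfr_sim` object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot cfr_sim
#' @export
autoplot.cfr_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(object$outer, -"outer_rep",
                              names_to = "kpi", values_to = "inner_mean")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$inner_mean)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::facet_wrap(~kpi, scales = "free_x") +
    ggplot2::labs(title = object$policy$label,
                  x = "inner mean (per outer replication)", y = "count") +
    ggplot2::theme_minimal()
}
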