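#' Plot posterior MMR trajectories
#'
#' District-faceted posterior-median MMR trajectories with 95% uncertainty
#' ribbons.
#'
#' @param object An `mmr_posterior` from [predict_mmr()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mmr_posterior <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$year, y = .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~district_id) +
    ggplot2::labs(x = NULL, y = "MMR (deaths per 100,000 live births)",
                  title = "Posterior district MMR trajectories") +
    ggplot2::theme_minimal()
}

#' Plot district-specific exposure slopes
#'
#' Point-interval display of each district's pooled total exposure slope
#' (fixed effect plus district random slope) with its 95% interval and a
#' zero reference line.
#'
#' @param object An `impact_result` fitted with a district exposure slope.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.impact_result <- function(object, ...) {
  slopes <- district_slope_report(object)
  ggplot2::ggplot(slopes,
                  ggplot2::aes(x = stats::reorder(.data$district_id, .data$estimate),
                               y = .data$estimate, colour = .data$excludes_zero)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper)) +
    ggplot2::coord_flip() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = NULL,
                  y = sprintf("district slope on %s (log-MMR scale)",
                              object$spec$exposure),
                  title = "District-specific exposure slopes") +
    ggplot2::theme_minimal()
}
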