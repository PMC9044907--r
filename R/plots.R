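#' Bar chart of single-marker and integrated predicted risk reductions
#'
#' One bar per scored marker subset (plus the integrated PRE-score row)
#' with its bootstrap confidence interval, faceted by outcome when the
#' result table covers more than one.
#'
#' @param results A `pre_result` tibble, e.g. from [score_all_markers()]
#'   or `run_pipeline()$results`.
#' @return A ggplot object.
#' @export
plot_rrr <- function(results) {
  df <- tidy.pre_result(results)
  df$label <- if ("label" %in% names(df)) df$label else df$marker_subset
  df$label <- factor(df$label, levels = unique(df$label))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$rrr_percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low_percent, ymax = .data$ci_high_percent),
      width = 0.25, na.rm = TRUE
    ) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "Predicted relative risk reduction (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (length(unique(df$outcome)) > 1) {
    p <- p + ggplot2::facet_wrap(~outcome)
  }
  p
}

#' @rdname plot_rrr
#' @param object A `pre_result`.
#' @param ... Unused.
#' @method autoplot pre_result
#' @export
autoplot.pre_result <- function(object, ...) plot_rrr(object)

#' Plot an RRR-versus-response scenario curve
#'
#' Predicted RRR against the realized placebo-corrected marker change, with
#' the bootstrap confidence band, as produced by [simulate_rrr_curve()].
#'
#' @param object A `pre_scenario_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pre_scenario_curve
#' @export
autoplot.pre_scenario_curve <- function(object, ...) {
  marker <- attr(object, "marker")
  xlab <- if (identical(attr(object, "transform"), "natural_log")) {
    paste0("Placebo-corrected ", marker, " reduction (%)")
  } else {
    paste0("Placebo-corrected ", marker, " change")
  }
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$change, y = .data$rrr_percent)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low_percent, ymax = .data$ci_high_percent),
      alpha = 0.2, fill = "steelblue"
    ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = xlab, y = "Predicted relative risk reduction (%)") +
    ggplot2::theme_minimal()
}
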