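#' Tornado diagram of the one-way sensitivity analysis
#'
#' @param object A `cua_dsa` result.
#' @param top Number of parameters to show, largest ICER spread first.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cua_dsa
#' @export
autoplot.cua_dsa <- function(object, top = 10, ...) {
  base_icer <- attr(object, "base_icer")
  df <- tibble::as_tibble(object) |>
    dplyr::filter(!.data$flagged) |>
    dplyr::slice_head(n = top) |>
    dplyr::mutate(parameter = factor(.data$parameter,
                                     levels = rev(.data$parameter)))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_icer, linetype = 2) +
    ggplot2::labs(x = "ICER (EUR/QALY)", y = NULL,
                  title = "One-way deterministic sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve
#'
#' @param object A `cua_psa` result.
#' @param ... Unused.
#' @return A ggplot of the probability of cost-effectiveness against
#'   willingness to pay.
#' @method autoplot cua_psa
#' @export
autoplot.cua_psa <- function(object, ...) {
  ggplot2::ggplot(object$ceac,
                  ggplot2::aes(.data$wtp, .data$prob_cost_effective)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1),
                                labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "Willingness to pay (EUR/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness plane scatterplot
#'
#' @param psa A `cua_psa` result.
#' @param wtp Willingness-to-pay threshold drawn as a reference line
#'   (EUR/QALY).
#' @return A ggplot of per-replication incremental cost vs incremental
#'   QALYs.
#' @export
plot_ce_plane <- function(psa, wtp = 50000) {
  ggplot2::ggplot(psa$reps, ggplot2::aes(.data$d_qaly, .data$d_cost)) +
    ggplot2::geom_point(alpha = 0.4, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (EUR)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}
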