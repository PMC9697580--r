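#' Paired RQ/SRF bar chart on a logarithmic scale
#'
#' One pair of bars per compound (risk quotient next to synthetic risk
#' factor) on a log10 value axis, with horizontal reference lines at the
#' band boundaries 0.01, 0.1 and 1. Risk values spanning many orders of
#' magnitude are unreadable on a linear axis, hence the log scale; values at
#' or below the axis floor (including a zero MEC) are drawn at the floor and
#' annotated rather than dropped.
#'
#' @param object An `srf_assessment` from [srf_assess()].
#' @param floor Lower axis limit; values below it are clamped and marked
#'   (default 1e-8).
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(srf_assess(srf_fixture("tianjin_bohai_pfc_ope")))
#' @method autoplot srf_assessment
#' @export
autoplot.srf_assessment <- function(object, floor = 1e-8, ...) {
  if (nrow(object) == 0) {
    abort_srftox("nothing-to-plot", "assessment has no rows to plot")
  }
  long <- tidy(object) |>
    dplyr::mutate(
      clamped = .data$value < floor,
      shown = pmax(.data$value, floor),
      name = factor(.data$name, levels = unique(object$name)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$name, y = .data$shown,
                                     fill = .data$method)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_hline(yintercept = c(0.01, 0.1, 1), linetype = "dashed",
                        linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_point(data = dplyr::filter(long, .data$clamped),
                        position = ggplot2::position_dodge(width = 0.8),
                        shape = 25, size = 2, show.legend = FALSE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "risk value (log scale)", fill = NULL,
                  caption = if (any(long$clamped))
                    sprintf("▽ below axis floor (%g)", floor)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot.srf_assessment
#' @param x An `srf_assessment`.
#' @export
plot_risk_comparison <- function(x, floor = 1e-8) {
  autoplot.srf_assessment(x, floor = floor)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
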