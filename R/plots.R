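#' Plot the Monte Carlo EDI distribution
#'
#' Density of the total estimated daily intake with the reported
#' percentiles marked.
#'
#' @param object An `edi_mcs` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot edi_mcs
#' @export
autoplot.edi_mcs <- function(object, ...) {
  pct <- dplyr::filter(object$percentiles, .data$congener == "total")
  ggplot2::ggplot(tibble::tibble(total = object$total),
                  ggplot2::aes(x = .data$total)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_vline(data = pct, linetype = "dashed",
                        ggplot2::aes(xintercept = .data$edi)) +
    ggplot2::labs(x = "Total EDI (ng/(kg day))", y = "Density",
                  title = "Simulated daily intake of Σ6 NDL-PCBs",
                  subtitle = "Dashed lines: 5/50/75/95th percentiles") +
    ggplot2::theme_minimal()
}

#' Plot the ILCR distribution against the acceptability threshold
#'
#' @param object An `ilcr_result` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ilcr_result
#' @export
autoplot.ilcr_result <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(ilcr = object$draws),
                  ggplot2::aes(x = .data$ilcr)) +
    ggplot2::geom_density(fill = "firebrick", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = object$limit, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ILCR (dimensionless, log scale)", y = "Density",
                  title = "Incremental lifetime cancer risk",
                  subtitle = paste0(object$statistic, " = ",
                                    format(object$summary_value, digits = 3),
                                    " (", object$classification, ")")) +
    ggplot2::theme_minimal()
}

#' Bar chart of congener contributions to the total intake
#'
#' @param contributions A tibble from [congener_contributions()].
#' @return A ggplot.
#' @export
plot_contributions <- function(contributions) {
  contributions$congener <- factor(contributions$congener,
                                   levels = contributions$congener)
  ggplot2::ggplot(contributions,
                  ggplot2::aes(x = .data$congener, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "Share of mean total EDI",
                  title = "Congener contributions to intake") +
    ggplot2::theme_minimal()
}
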