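#' Plot predicted versus measured affinity
#'
#' Scatter of predicted against measured \eqn{-\ln K_D}, absolute scale
#' (one point per allele) and relative \eqn{\Delta\ln K_D} scale (one
#' point per SNP), with an ordinary-least-squares line and its 95%
#' confidence band.
#'
#' @param comparison Comparison table from [build_comparison()].
#' @return A ggplot object.
#' @export
#' @examples
#' plot_validation()
plot_validation <- function(comparison = build_comparison()) {
  absolute <- comparison %>%
    select(predicted = "predicted_neglog_kd",
           measured = "measured_neglog_kd") %>%
    mutate(scale = "absolute (-ln K_D)")
  deltas <- comparison %>%
    distinct(.data$gene_id, .data$rsid, .data$predicted_delta,
             .data$measured_delta) %>%
    select(predicted = "predicted_delta", measured = "measured_delta") %>%
    mutate(scale = "relative (delta ln K_D)")
  dat <- bind_rows(absolute, deltas)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$predicted,
                                    y = .data$measured)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, level = 0.95,
                         colour = "grey30", fill = "grey80",
                         linewidth = 0.5) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~scale, scales = "free") +
    ggplot2::labs(x = "predicted (ln units)", y = "measured (ln units)") +
    ggplot2::theme_bw()
}

#' Plot a saturation-binding fit
#'
#' Observed rates against ODN concentration with the fitted one-site
#' saturation curve.
#'
#' @param x A `tbp_kd_fit` from [fit_kd()].
#' @return A ggplot object.
#' @export
plot_kinetics <- function(x) {
  stopifnot(inherits(x, "tbp_kd_fit"))
  curve <- tibble::tibble(
    conc_nM = seq(0, max(x$data$conc_nM) * 1.05, length.out = 200))
  curve$rate <- x$vmax * curve$conc_nM / (x$kd_nM + curve$conc_nM)
  ggplot2::ggplot(x$data, ggplot2::aes(x = .data$conc_nM,
                                       y = .data$rate)) +
    ggplot2::geom_line(data = curve, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "ODN concentration (nM)", y = "reaction rate",
                  subtitle = sprintf("K_D = %.3g +/- %.2g nM",
                                     x$kd_nM, x$kd_sem)) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plot_kinetics
#' @param object A `tbp_kd_fit`.
#' @param ... Unused.
#' @method autoplot tbp_kd_fit
#' @export
autoplot.tbp_kd_fit <- function(object, ...) plot_kinetics(object)
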