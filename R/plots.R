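#' Plot the CTA timing analysis
#'
#' Reproduces the timing-analysis figure style: the dynamic AIF, VOF and
#' (optionally) FOV-mean curves, the AIF-minus-VOF difference curve, the
#' constant CTA HU levels as horizontal dotted lines, and the estimated
#' acquisition time as a vertical line.
#'
#' @param aif,vof Curve tibbles (`time_s`, `hu`, `label`).
#' @param cta_values Named vector `c(arterial = , venous = )`.
#' @param estimate Optional `phase_estimate` from [estimate_timing()].
#' @param fov Optional FOV-mean curve tibble.
#' @return A ggplot object.
#' @export
plot_timing <- function(aif, vof, cta_values, estimate = NULL, fov = NULL) {
  diff <- difference_curve(aif, vof)
  curves <- dplyr::bind_rows(aif, vof, diff, fov)
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$time_s, y = .data$hu,
                                    colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = unname(cta_values["arterial"]),
                        linetype = "dotted") +
    ggplot2::geom_hline(yintercept = unname(cta_values["venous"]),
                        linetype = "dotted") +
    ggplot2::geom_hline(
      yintercept = unname(cta_values["arterial"] - cta_values["venous"]),
      linetype = "dotted", colour = "grey40") +
    ggplot2::labs(x = "Time (s)", y = "Attenuation (HU)", colour = NULL)
  if (!is.null(estimate))
    p <- p + ggplot2::geom_vline(xintercept = estimate$t_est,
                                 linetype = "dashed") +
      ggplot2::ggtitle(sprintf("Estimated acquisition: %.1f s (%s)",
                               estimate$t_est, as.character(estimate$phase)))
  p
}

#' Bland-Altman plot with percentile limits
#'
#' Solid line at the mean difference; dotted lines at the 2.5th and 97.5th
#' percentiles of the differences.
#'
#' @param object A `bland_altman` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bland_altman <- function(object, ...) {
  df <- tibble::tibble(mean = attr(object, "means"),
                       diff = attr(object, "differences"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$mean_diff) +
    ggplot2::geom_hline(yintercept = c(object$lo, object$hi),
                        linetype = "dotted") +
    ggplot2::labs(x = "Mean of methods (mL)", y = "Difference (mL)")
}

#' Per-stratum correlation overview for a stratified report
#'
#' Pearson r with 95% CI per stratum, faceted by presentation window.
#'
#' @param object A `stratified_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.stratified_report <- function(object, ...) {
  ev <- dplyr::filter(object$agreement, .data$evaluable)
  ev$stratum <- paste(ev$stratifier, ev$group)
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$r, y = .data$stratum)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$r_lo, xmax = .data$r_hi),
                            height = 0.2) +
    ggplot2::facet_wrap(~window) +
    ggplot2::labs(x = "Pearson r (95% CI)", y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
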