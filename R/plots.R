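# ggplot2 views of the result types.

#' Plot a heart-current-factor table
#'
#' Lines of the chosen statistic over frequency (DC shown at the left edge
#' of the log axis), one line per current path.
#'
#' @param object An `hcf_table`.
#' @param statistic `"f99"` or `"f_sam"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hcf_table <- function(object, statistic = c("f99", "f_sam"), ...) {
  statistic <- match.arg(statistic)
  df <- tibble::as_tibble(object)
  fpos <- sort(unique(df$frequency))
  fmin_pos <- min(fpos[fpos > 0], 10)
  df$f_plot <- ifelse(df$frequency == 0, fmin_pos / 10, df$frequency)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f_plot,
                                   y = .data[[statistic]],
                                   colour = .data$path)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "frequency (Hz; leftmost point = DC)",
                  y = paste0("heart current factor (", statistic, ")"),
                  colour = "path") +
    ggplot2::theme_minimal()
}

#' Plot |Z| versus frequency from a dose report
#'
#' @param dose Dose tibble from [compute_dose()] / [run_campaign()].
#' @return A ggplot object (log-log, one line per path and mode).
#' @export
plot_impedance <- function(dose) {
  df <- dose
  fpos <- sort(unique(df$frequency))
  fmin_pos <- min(fpos[fpos > 0], 10)
  df$f_plot <- ifelse(df$frequency == 0, fmin_pos / 10, df$frequency)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f_plot, y = .data$z_total_ohm,
                                   colour = .data$path,
                                   linetype = .data$mode)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz; leftmost point = DC)",
                  y = "|Z| (Ohm)") +
    ggplot2::theme_minimal()
}

#' Plot a fitted skin-slice property set
#'
#' @param object A `skin_fit`.
#' @param ... Unused.
#' @return A ggplot object: sigma and eps_r versus touch voltage.
#' @export
autoplot.skin_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object), c("sigma", "eps_r"),
                            names_to = "property")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$touch_voltage, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~property, scales = "free_y") +
    ggplot2::labs(x = "touch voltage (V)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
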