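# Diagnostic figures: agreement scatter, Bland-Altman, equivalents series.

#' Predicted-versus-reference agreement plot
#'
#' Scatter of predicted against reference values with the identity and the
#' fitted regression line.
#'
#' @param pred,ref paired values.
#' @return a ggplot object.
#' @export
plot_agreement <- function(pred, ref) {
  df <- data.frame(ref = ref, pred = pred)
  ggplot2::ggplot(df, ggplot2::aes(x = ref, y = pred)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6, colour = "firebrick") +
    ggplot2::labs(x = "reference EE (kcal/min)",
                  y = "predicted EE (kcal/min)")
}

#' Bland-Altman plot
#'
#' @param ba a [bland_altman()] result.
#' @return a ggplot object with bias (solid) and limits of agreement
#'   (dashed).
#' @export
plot_bland_altman <- function(ba) {
  stopifnot(inherits(ba, "bland_altman"))
  ggplot2::ggplot(ba$data, ggplot2::aes(x = avg, y = diff)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_hline(yintercept = ba$bias) +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "average EE (kcal/min)",
                  y = "difference, predicted - reference (kcal/min)")
}

#' Respiratory-equivalents plot with detected thresholds
#'
#' @param series a [compute_equivalents()] series.
#' @param partition optional [detect_thresholds()] partition; adds vertical
#'   lines at the two thresholds.
#' @return a ggplot object.
#' @export
plot_equivalents <- function(series, partition = NULL) {
  df <- rbind(data.frame(t = series$t, value = series$eq_o2,
                         equivalent = "VE/VO2"),
              data.frame(t = series$t, value = series$eq_co2,
                         equivalent = "VE/VCO2"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = t, y = value,
                                        colour = equivalent)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "ventilatory equivalent")
  if (!is.null(partition))
    p <- p + ggplot2::geom_vline(xintercept = c(partition$t_th1,
                                                partition$t_th2),
                                 linetype = "dotted")
  p
}
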