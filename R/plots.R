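#' Plot posterior torque-angle curve draws
#'
#' Posterior-mean torque with an equal-tailed credible ribbon. Extension
#' curves recorded on the anatomical flexion axis can be displayed on the
#' extension-progress axis (0 at the start of the action) with
#' `rescale = TRUE`.
#'
#' @param object A `"curve_draws"` object.
#' @param level Credible level. Default 0.95.
#' @param rescale Display on the extension-progress axis. Default `FALSE`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.curve_draws <- function(object, level = 0.95, rescale = FALSE, ...) {
  df <- tidy(object, level = level)
  xlab <- "knee flexion angle (deg)"
  if (rescale) {
    df$angle <- rescale_extension_angle(df$angle)
    df <- df[order(df$angle), , drop = FALSE]
    xlab <- "extension progress (deg)"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$angle, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = xlab, y = "moment of force (N·m)",
      title = if (!is.null(object$action)) {
        paste(object$action, object$mode, sep = " / ")
      }
    ) +
    ggplot2::theme_minimal()
}

#' Plot a functional H:Q ratio curve
#'
#' Posterior-mean ratio with its 95% credible ribbon and the reference
#' (point-of-equality) line; detected crossings are marked.
#'
#' @param object A `"ratio_curve"` object.
#' @param rescale Display on the extension-progress axis. Default `FALSE`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ratio_curve <- function(object, rescale = FALSE, ...) {
  df <- tidy(object)
  crossings <- object$crossings
  xlab <- "knee flexion angle (deg)"
  if (rescale) {
    df$angle <- rescale_extension_angle(df$angle)
    df <- df[order(df$angle), , drop = FALSE]
    crossings <- rescale_extension_angle(crossings)
    xlab <- "extension progress (deg)"
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$angle, y = .data$mean)) +
    ggplot2::geom_hline(yintercept = object$level, linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = "functional H:Q ratio") +
    ggplot2::theme_minimal()
  if (length(crossings)) {
    p <- p + ggplot2::geom_vline(xintercept = crossings, linetype = 3)
  }
  p
}
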