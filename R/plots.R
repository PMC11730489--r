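#' Plot loss curves with regression-line overlays
#'
#' Draws the generator and discriminator loss curves and overlays the OLS
#' regression lines of an analysis (full-range solid, stable-segment dashed),
#' the standard monitoring figure for a training run.
#'
#' @param history A loss history.
#' @param regressions Optional list of `loss_regression` objects to overlay
#'   (e.g. `analyze_history(h)$regressions`).
#' @return A ggplot object.
#' @export
plot_loss_curves <- function(history, regressions = NULL) {
  history <- as_loss_history(history)
  long <- tidyr::pivot_longer(history, c("g_loss", "d_loss"),
                              names_to = "channel", values_to = "loss")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$loss,
                                          colour = .data$channel)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "epoch", y = "loss (nats)", colour = NULL,
                  linetype = "regression") +
    ggplot2::theme_minimal()
  if (!is.null(regressions)) {
    seg <- purrr::map_dfr(regressions, function(r) {
      tibble::tibble(
        channel = r$channel, start = r$start_epoch, end = r$end_epoch,
        y0 = r$intercept + r$slope * r$start_epoch,
        y1 = r$intercept + r$slope * r$end_epoch,
        interval = sprintf("%d-%d", r$start_epoch, r$end_epoch)
      )
    })
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$start, xend = .data$end, y = .data$y0,
                   yend = .data$y1, colour = .data$channel,
                   linetype = .data$interval),
      inherit.aes = FALSE, linewidth = 0.8
    )
  }
  p
}

#' @export
autoplot.loss_history <- function(object, ...) plot_loss_curves(object, ...)

#' Plot an epoch-slope curve
#'
#' Cumulative regression slope against its right endpoint: the diagnostic on
#' which the stop rule operates. The near-horizontal band `±flat_tol` is
#' shaded when supplied.
#'
#' @param object A `slope_series`.
#' @param flat_tol Optional band half-width to shade.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.slope_series <- function(object, flat_tol = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$right_epoch, .data$slope)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(
      x = "right endpoint epoch",
      y = sprintf("slope of regression from epoch %d (nats/epoch)",
                  object$anchor_epoch[1])
    ) +
    ggplot2::theme_minimal()
  if (!is.null(flat_tol)) {
    p <- p + ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                               ymin = -flat_tol, ymax = flat_tol,
                               alpha = 0.15, fill = "#31a354")
  }
  p
}

#' @export
autoplot.gan_analysis <- function(object, ...) {
  plot_loss_curves(object$history, object$regressions)
}
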