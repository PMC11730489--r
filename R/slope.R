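#' Ordinary-least-squares fit over a loss-history segment
#'
#' Fits `loss = slope * epoch + intercept` by least squares over the epochs
#' in `[start_epoch, end_epoch]` (inclusive) of one loss channel. This is the
#' elementary operation of the whole analysis: regression slopes over full
#' histories, over trimmed stable segments, and over expanding or rolling
#' windows are all instances of it. Segments with fewer than 5 points warn
#' (short segments are ill-conditioned); fewer than 2 points is an error.
#'
#' @param history A loss history (data frame with `epoch,g_loss,d_loss`).
#' @param channel `"g_loss"` or `"d_loss"`.
#' @param start_epoch,end_epoch Inclusive segment bounds (defaults: full
#'   range).
#' @return A `loss_regression` object with fields `slope` (nats/epoch),
#'   `intercept` (nats), `start_epoch`, `end_epoch`, `channel`, `n`,
#'   `std_error` (of the slope), `r_squared`. Supports `tidy()`/`glance()`.
#' @examples
#' h <- simulate_loss_history(archetype_params("A2_peak_then_plateau"))
#' fit_loss_line(h, "g_loss", 150, 499)
#' @export
fit_loss_line <- function(history, channel = c("g_loss", "d_loss"),
                          start_epoch = NULL, end_epoch = NULL) {
  channel <- match.arg(channel)
  history <- as_loss_history(history)
  start_epoch <- start_epoch %||% min(history$epoch)
  end_epoch <- end_epoch %||% max(history$epoch)
  if (end_epoch <= start_epoch) {
    rlang::abort("end_epoch must exceed start_epoch",
                 class = "ganstop_segment_error")
  }
  seg <- dplyr::filter(history, .data$epoch >= start_epoch,
                       .data$epoch <= end_epoch)
  if (nrow(seg) < 2) {
    rlang::abort(sprintf(
      "segment [%s, %s] has %d point(s); at least 2 are required",
      format(start_epoch), format(end_epoch), nrow(seg)
    ), class = "ganstop_segment_error")
  }
  if (nrow(seg) < 5) {
    rlang::warn(sprintf(
      "segment has only %d points; regressions over fewer than 5 points are poorly conditioned",
      nrow(seg)
    ), class = "ganstop_short_segment")
  }
  x <- as.numeric(seg$epoch)
  y <- seg[[channel]]
  fit <- stats::lm.fit(cbind(intercept = 1, epoch = x), y)
  slope <- unname(fit$coefficients["epoch"])
  intercept <- unname(fit$coefficients["intercept"])
  n <- length(y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  sxx <- sum((x - mean(x))^2)
  se <- if (n > 2) sqrt(rss / (n - 2) / sxx) else NA_real_
  structure(list(
    slope = slope, intercept = intercept,
    start_epoch = as.integer(start_epoch), end_epoch = as.integer(end_epoch),
    channel = channel, n = n, std_error = se,
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_
  ), class = "loss_regression")
}

#' @export
print.loss_regression <- function(x, ...) {
  cat(sprintf("<loss_regression %s [%d, %d]> Y = %.5f X + %.5f  (n = %d)\n",
              x$channel, x$start_epoch, x$end_epoch, x$slope, x$intercept, x$n))
  invisible(x)
}

#' Cumulative slope series from a fixed anchor epoch
#'
#' For every right endpoint `n` from `anchor_epoch + 5` to the last recorded
#' epoch, computes the OLS slope of the channel over `[anchor_epoch, n]`
#' (inclusive). The first computable entry therefore uses 6 points; histories
#' extending fewer than 5 epochs past the anchor are rejected (regressions on
#' shorter segments are poorly conditioned). Slopes are computed with exact
#' prefix-sum algebra, identical to [fit_loss_line()] on each segment.
#'
#' @param history A loss history.
#' @param channel `"g_loss"` or `"d_loss"`.
#' @param anchor_epoch Left endpoint of every regression (default 0; a
#'   trimmed analysis anchors at the stable-segment start, e.g. 150).
#' @return A `slope_series` tibble with columns `anchor_epoch`,
#'   `right_epoch`, `slope`, `channel`.
#' @export
slope_series <- function(history, channel = c("g_loss", "d_loss"),
                         anchor_epoch = 0) {
  channel <- match.arg(channel)
  history <- as_loss_history(history)
  idx <- which(history$epoch >= anchor_epoch)
  if (length(idx) == 0 ||
        max(history$epoch) < anchor_epoch + 5) {
    rlang::abort(sprintf(
      "history must extend at least 5 epochs past the anchor (%s): regressions on fewer points are poorly conditioned",
      format(anchor_epoch)
    ), class = "ganstop_segment_error")
  }
  x <- as.numeric(history$epoch[idx])
  y <- history[[channel]][idx]
  k <- seq_along(x)
  sx <- cumsum(x); sy <- cumsum(y)
  sxx <- cumsum(x^2); sxy <- cumsum(x * y)
  slope <- (k * sxy - sx * sy) / (k * sxx - sx^2)
  keep <- x >= anchor_epoch + 5
  out <- tibble::tibble(
    anchor_epoch = as.integer(anchor_epoch),
    right_epoch = as.integer(x[keep]),
    slope = slope[keep],
    channel = channel
  )
  class(out) <- c("slope_series", class(tibble::tibble()))
  out
}

# centered rolling OLS slope over windows of `w` consecutive points (unit
# x-spacing); NA at the edges. `w` is made odd internally so the window has
# an exact center.
rolling_slope <- function(y, w) {
  w <- as.integer(w)
  if (w %% 2L == 0L) w <- w + 1L
  wts <- seq_len(w) - (w + 1) / 2
  num <- stats::filter(y, rev(wts) / sum(wts^2), sides = 2)
  as.numeric(num)
}

moving_average <- function(y, w) {
  as.numeric(stats::filter(y, rep(1 / w, w), sides = 2))
}
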