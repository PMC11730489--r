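#' Detect the start of the stable loss segment
#'
#' Programmatic replacement for eyeballing the loss curve: after the
#' rise-and-fall transient that healthy runs show early in training, the
#' generator loss settles into a flat band. The rule: smooth the channel with
#' a centered moving average of `smooth_window` epochs, locate the global
#' maximum of the smoothed series, then return the first epoch after it at
#' which the centered rolling OLS slope of the smoothed series stays within
#' `±flat_tol` for `smooth_window` consecutive epochs. A series that is flat
#' from the start returns its first epoch; `override` bypasses detection.
#'
#' @param history A loss history.
#' @param channel `"g_loss"` (default) or `"d_loss"`.
#' @param smooth_window Moving-average and rolling-slope window, epochs
#'   (default 25).
#' @param flat_tol Band half-width counted as flat, nats/epoch
#'   (default 0.005).
#' @param override Optional user-supplied stable-start epoch returned as-is.
#' @return The stable-start epoch (integer). When no epoch qualifies,
#'   `NA_integer_` with attribute `reason = "no_stable_segment"`.
#' @export
detect_stable_start <- function(history, channel = c("g_loss", "d_loss"),
                                smooth_window = 25, flat_tol = 0.005,
                                override = NULL) {
  channel <- match.arg(channel)
  if (!is.null(override)) return(as.integer(override))
  history <- as_loss_history(history)
  if (nrow(history) <= 2 * smooth_window) {
    abort_config(sprintf(
      "history length (%d) must exceed 2 x smooth_window (%d)",
      nrow(history), 2 * smooth_window
    ))
  }
  y <- history[[channel]]
  sm <- moving_average(y, smooth_window)
  rs <- rolling_slope(sm, smooth_window)
  in_band <- !is.na(rs) & abs(rs) <= flat_tol
  peak_i <- which.max(sm)

  no_stable <- function() {
    structure(NA_integer_, reason = "no_stable_segment")
  }
  first_run_start <- function(candidates) {
    for (i in candidates) {
      if (all(in_band[i:(i + smooth_window - 1)])) return(i)
    }
    NULL
  }

  # flat from the start: every defined rolling slope in band and the smoothed
  # maximum inside the first window
  defined <- which(!is.na(rs))
  if (length(defined) && all(in_band[defined]) && peak_i <= smooth_window) {
    return(history$epoch[1])
  }
  upper <- nrow(history) - smooth_window + 1L
  if (peak_i + 1L > upper) return(no_stable())
  i <- first_run_start(seq.int(peak_i + 1L, upper))
  if (is.null(i)) return(no_stable()) else history$epoch[i]
}

#' Recommend a training stop epoch from the loss history
#'
#' Implements the stopping rule: anchor a cumulative slope series at the
#' detected stable-segment start and stop once the generator-loss slope has
#' transitioned from negative (below `-flat_tol`) to near-horizontal or
#' positive (at or above `-flat_tol`) and stayed there for `persistence`
#' consecutive endpoints; the recommended epoch is the endpoint at which that
#' persistence is confirmed. A series that is flat-stable from the anchor
#' with no negative phase stops at `anchor + persistence`
#' (`plateau_stability`); if the slope never stabilizes there is no
#' recommendation.
#'
#' @param history A loss history.
#' @param flat_tol Near-horizontal band half-width, nats/epoch
#'   (default 0.005).
#' @param persistence Consecutive stable endpoints required (default 25).
#' @param smooth_window Passed to [detect_stable_start()] (default 25).
#' @param stable_start Optional anchor override.
#' @param channel Deciding channel (default `"g_loss"`; the discriminator
#'   channel is reported alongside but does not decide).
#' @return A `stop_recommendation`: list with `stop_epoch` (integer or NA),
#'   `rationale` (`"slope_sign_transition"`, `"plateau_stability"` or
#'   `"no_stable_segment"`), `stable_start`, `slope_at_stop`, `channel`.
#' @examples
#' h <- simulate_loss_history(archetype_params("A2_peak_then_plateau"))
#' recommend_stop(h)
#' @export
recommend_stop <- function(history, flat_tol = 0.005, persistence = 25,
                           smooth_window = 25, stable_start = NULL,
                           channel = c("g_loss", "d_loss")) {
  channel <- match.arg(channel)
  history <- as_loss_history(history)
  anchor <- if (is.null(stable_start)) {
    detect_stable_start(history, channel, smooth_window, flat_tol)
  } else as.integer(stable_start)

  none <- function(anch) {
    structure(list(stop_epoch = NA_integer_, rationale = "no_stable_segment",
                   stable_start = anch, slope_at_stop = NA_real_,
                   channel = channel),
              class = "stop_recommendation")
  }
  if (is.na(anchor)) return(none(NA_integer_))

  ss <- slope_series(history, channel, anchor)
  s <- ss$slope
  ok <- s >= -flat_tol
  had_neg <- cumsum(!ok) > 0   # a sub -flat_tol endpoint seen before i

  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in seq_along(runs$lengths)) {
    if (!runs$values[r] || runs$lengths[r] < persistence) next
    a <- starts[r]
    confirm <- a + persistence - 1L
    if (a > 1 && had_neg[a]) {
      return(structure(list(
        stop_epoch = ss$right_epoch[confirm],
        rationale = "slope_sign_transition",
        stable_start = as.integer(anchor),
        slope_at_stop = s[confirm], channel = channel
      ), class = "stop_recommendation"))
    }
    if (a == 1) {
      # flat-stable from the anchor, no preceding negative phase
      stop_epoch <- as.integer(anchor + persistence)
      below <- which(ss$right_epoch <= stop_epoch)
      j <- if (length(below)) max(below) else 1L
      return(structure(list(
        stop_epoch = stop_epoch, rationale = "plateau_stability",
        stable_start = as.integer(anchor),
        slope_at_stop = s[j], channel = channel
      ), class = "stop_recommendation"))
    }
  }
  none(as.integer(anchor))
}

#' @export
print.stop_recommendation <- function(x, ...) {
  if (is.na(x$stop_epoch)) {
    cat(sprintf("<stop_recommendation> none (%s)\n", x$rationale))
  } else {
    cat(sprintf(
      "<stop_recommendation> stop at epoch %d (%s; stable segment from %d; slope %.5f)\n",
      x$stop_epoch, x$rationale, x$stable_start, x$slope_at_stop
    ))
  }
  invisible(x)
}

#' Detect late training divergence (failed run)
#'
#' A failed run keeps the early rise-and-fall shape but the generator loss
#' begins a sustained climb late in training, after which the generator no
#' longer produces meaningful images. The detector computes the centered
#' rolling OLS slope of the raw generator loss over `trail_window`-epoch
#' windows and flags divergence when the slope exceeds `rise_tol` for at
#' least `trail_window / 2` consecutive epochs after the stable-segment
#' start (all epochs, when no stable segment exists). The onset is the first
#' epoch of that sustained run.
#'
#' @param history A loss history.
#' @param trail_window Rolling window length in epochs (default 50).
#' @param rise_tol Slope threshold, nats/epoch (default 0.01).
#' @param stable_start Optional stable-start override.
#' @param channel Channel examined (default `"g_loss"`).
#' @return A `divergence_report`: list with `diverged` (flag), `onset_epoch`
#'   (integer, NA unless diverged), `trailing_slope` (last defined rolling
#'   slope), `channel`.
#' @export
detect_divergence <- function(history, trail_window = 50, rise_tol = 0.01,
                              stable_start = NULL,
                              channel = c("g_loss", "d_loss")) {
  channel <- match.arg(channel)
  history <- as_loss_history(history)
  if (nrow(history) <= trail_window) {
    abort_config(sprintf("history length (%d) must exceed trail_window (%d)",
                         nrow(history), trail_window))
  }
  y <- history[[channel]]
  rs <- rolling_slope(y, trail_window)
  anchor <- if (is.null(stable_start)) {
    tryCatch(
      suppressWarnings(detect_stable_start(history, channel)),
      ganstop_config_error = function(e) NA_integer_
    )
  } else as.integer(stable_start)

  eligible <- if (is.na(anchor)) rep(TRUE, nrow(history)) else
    history$epoch > anchor
  hot <- !is.na(rs) & rs > rise_tol & eligible
  need <- max(1L, as.integer(trail_window / 2))
  runs <- rle(hot)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  onset <- NA_integer_
  for (r in seq_along(runs$lengths)) {
    if (runs$values[r] && runs$lengths[r] >= need) {
      onset <- history$epoch[starts[r]]
      break
    }
  }
  trailing <- rs[max(which(!is.na(rs)))]
  structure(list(diverged = !is.na(onset), onset_epoch = onset,
                 trailing_slope = trailing, channel = channel),
            class = "divergence_report")
}

#' @export
print.divergence_report <- function(x, ...) {
  if (x$diverged) {
    cat(sprintf(
      "<divergence_report> DIVERGED: sustained %s rise from epoch %d (trailing slope %.5f)\n",
      x$channel, x$onset_epoch, x$trailing_slope
    ))
  } else {
    cat(sprintf("<divergence_report> no divergence (trailing slope %.5f)\n",
                x$trailing_slope))
  }
  invisible(x)
}
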