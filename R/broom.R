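#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Broom-style accessors for fitted loss regressions
#'
#' `tidy()` returns the coefficient table; `glance()` a one-row model
#' summary.
#'
#' @param x A `loss_regression`.
#' @param ... Ignored.
#' @return A tibble.
#' @export
tidy.loss_regression <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "epoch"),
    estimate = c(x$intercept, x$slope),
    std.error = c(NA_real_, x$std_error)
  )
}

#' @rdname tidy.loss_regression
#' @export
glance.loss_regression <- function(x, ...) {
  tibble::tibble(
    channel = x$channel, start_epoch = x$start_epoch,
    end_epoch = x$end_epoch, slope = x$slope, intercept = x$intercept,
    r.squared = x$r_squared, nobs = x$n
  )
}

#' Broom-style accessors for parameter counts
#'
#' `tidy()` returns the per-layer parameter table; `glance()` the totals.
#'
#' @param x A `param_count` from [count_parameters()].
#' @param ... Ignored.
#' @return A tibble.
#' @export
tidy.param_count <- function(x, ...) x$per_layer

#' @rdname tidy.param_count
#' @export
glance.param_count <- function(x, ...) {
  tibble::tibble(total = x$total, trainable = x$trainable,
                 non_trainable = x$non_trainable)
}

#' @export
glance.stop_recommendation <- function(x, ...) {
  tibble::tibble(stop_epoch = x$stop_epoch, rationale = x$rationale,
                 stable_start = x$stable_start,
                 slope_at_stop = x$slope_at_stop, channel = x$channel)
}

#' @export
glance.divergence_report <- function(x, ...) {
  tibble::tibble(diverged = x$diverged, onset_epoch = x$onset_epoch,
                 trailing_slope = x$trailing_slope, channel = x$channel)
}
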