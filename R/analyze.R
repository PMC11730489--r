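#' Full post-hoc analysis of a loss history
#'
#' Runs the whole slope pipeline on one history: descriptive statistics for
#' both channels, full-range OLS regression lines for both channels, the
#' stable-segment start, a trimmed regression over the stable segment, the
#' stop recommendation and the divergence report. This is what the `analyze`
#' CLI subcommand computes and serializes.
#'
#' @param history A loss history (or path handled by the caller).
#' @param flat_tol,persistence,smooth_window Stop-rule thresholds (see
#'   [recommend_stop()]).
#' @param trail_window,rise_tol Divergence thresholds (see
#'   [detect_divergence()]).
#' @param stable_start Optional stable-start override applied everywhere.
#' @return A `gan_analysis` list: `summaries` (tibble), `regressions` (named
#'   list of `loss_regression`), `stable_start`, `stop`
#'   (`stop_recommendation`), `divergence` (`divergence_report`),
#'   `thresholds`.
#' @examples
#' h <- simulate_loss_history(archetype_params("A2"), rng_seed = 3)
#' analyze_history(h)
#' @export
analyze_history <- function(history, flat_tol = 0.005, persistence = 25,
                            smooth_window = 25, trail_window = 50,
                            rise_tol = 0.01, stable_start = NULL) {
  history <- as_loss_history(history)
  if (nrow(history) < 6) {
    rlang::abort(paste0(
      "loss history has only ", nrow(history), " epochs; slope analysis ",
      "needs at least 5 epochs beyond the first (regressions over fewer ",
      "points are poorly conditioned)"
    ), class = "ganstop_segment_error")
  }
  anchor <- if (is.null(stable_start)) {
    detect_stable_start(history, "g_loss", smooth_window, flat_tol)
  } else as.integer(stable_start)

  regs <- list(
    g_full = fit_loss_line(history, "g_loss"),
    d_full = fit_loss_line(history, "d_loss")
  )
  if (!is.na(anchor) && max(history$epoch) >= anchor + 5) {
    regs$g_stable <- fit_loss_line(history, "g_loss", anchor, max(history$epoch))
    regs$d_stable <- fit_loss_line(history, "d_loss", anchor, max(history$epoch))
  }
  structure(list(
    summaries = loss_summary(history),
    regressions = regs,
    stable_start = anchor,
    stop = recommend_stop(history, flat_tol, persistence, smooth_window,
                          stable_start = if (is.na(anchor)) NULL else anchor),
    divergence = detect_divergence(history, trail_window, rise_tol,
                                   stable_start = if (is.na(anchor)) NULL else anchor),
    thresholds = list(flat_tol = flat_tol, persistence = persistence,
                      smooth_window = smooth_window,
                      trail_window = trail_window, rise_tol = rise_tol),
    history = history
  ), class = "gan_analysis")
}

#' @export
print.gan_analysis <- function(x, ...) {
  cat("<gan_analysis>\n")
  print(as.data.frame(x$summaries), row.names = FALSE)
  for (r in x$regressions) print(r)
  cat(sprintf("stable segment start: %s\n",
              if (is.na(x$stable_start)) "none" else x$stable_start))
  print(x$stop)
  print(x$divergence)
  invisible(x)
}

#' Serialize an analysis to a report JSON file
#'
#' Writes a deterministic JSON document (regressions, stable start, stop
#' recommendation, divergence report, summaries, thresholds); repeated calls
#' on the same inputs produce byte-identical files.
#'
#' @param analysis A `gan_analysis` from [analyze_history()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(analysis, path) {
  stopifnot(inherits(analysis, "gan_analysis"))
  reg <- purrr::map(analysis$regressions, function(r) {
    r[c("channel", "start_epoch", "end_epoch", "slope", "intercept", "n",
        "r_squared")]
  })
  doc <- list(
    summaries = analysis$summaries,
    regressions = reg,
    stable_start = analysis$stable_start,
    stop = unclass(analysis$stop),
    divergence = unclass(analysis$divergence),
    thresholds = analysis$thresholds
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = 10,
                       na = "null", pretty = TRUE)
  invisible(path)
}
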